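#' Configuration of the synthetic MEA recording generator
#'
#' Defines how per-electrode per-trial evoked spike counts are produced
#' from a latent learning network. Defaults emulate control-condition
#' cultures: roughly 44 usable electrodes split into source-1-preferring,
#' source-2-preferring and no-preference groups, a mean evoked response
#' around 3 spikes/trial, mildly overdispersed counts and a slow linear
#' drift across sessions.
#'
#' Conditions map onto the implicit state prior of the latent network:
#' \code{control} uses a balanced prior (ON expectation 0.5),
#' \code{bicuculline} (GABA-A antagonist, hyper-excitable) an ON
#' expectation of 0.8 with a raised baseline rate, \code{diazepam}
#' (agonist, hypo-excitable) 0.2 with a lowered baseline, and \code{apv}
#' (NMDA-receptor antagonist) the control prior with plasticity slowed by
#' a large inverse learning rate. \code{mix0} and \code{mix50} keep the
#' control prior but change the stimulus mixing fraction.
#'
#' @param n_electrodes number of recorded electrodes.
#' @param group_fractions named fractions over \code{source1},
#'   \code{source2}, \code{none}; must sum to 1.
#' @param baseline_rate baseline evoked rate (spikes/trial); overridden by
#'   condition-specific values when \code{NULL}.
#' @param gain spikes/trial per unit latent response.
#' @param baseline_jitter_sd,gain_jitter_sd lognormal spread of
#'   per-electrode baselines and gains (real MEA electrodes are very
#'   heterogeneous in evoked-response strength).
#' @param n_direct_inputs number of stimulation channels each
#'   no-preference electrode is directly driven by (drawn at random per
#'   electrode).
#' @param noise_dispersion negative-binomial size parameter (larger =
#'   closer to Poisson).
#' @param trend_slope additive drift in spikes/trial per session.
#' @param condition one of \code{"control"}, \code{"bicuculline"},
#'   \code{"diazepam"}, \code{"apv"}, \code{"mix0"}, \code{"mix50"}.
#' @param plasticity_lambda inverse learning rate passed to the latent
#'   network (condition default when \code{NULL}; large for \code{apv}).
#' @param seed integer seed for the synthetic noise stream.
#' @return object of class \code{synthetic_config}.
#' @export
synthetic_config <- function(n_electrodes = 44L,
                             group_fractions = c(source1 = 0.39,
                                                 source2 = 0.34,
                                                 none = 0.27),
                             baseline_rate = NULL,
                             gain = 3,
                             baseline_jitter_sd = 0.2,
                             gain_jitter_sd = 0.4,
                             n_direct_inputs = 4L,
                             noise_dispersion = 20,
                             trend_slope = 0.003,
                             condition = c("control", "bicuculline",
                                           "diazepam", "apv", "mix0",
                                           "mix50"),
                             plasticity_lambda = NULL,
                             seed = 1L) {
  condition <- match.arg(condition)
  if (abs(sum(group_fractions) - 1) > 1e-8)
    stop("group_fractions must sum to 1")
  if (any(group_fractions < 0)) stop("group_fractions must be nonnegative")
  # Condition defaults: baselines track reported mean response intensities
  # (control ~3.0, bicuculline ~3.7, diazepam ~2.3 spikes/trial with the
  # latent contribution included).
  # Baselines chosen so the grand-mean evoked response per condition lands
  # near the reported intensities (about 3.0 control, 3.7 bicuculline,
  # 2.3 diazepam spikes/trial) once the latent contribution is added.
  if (is.null(baseline_rate))
    baseline_rate <- switch(condition,
                            bicuculline = 1.8, diazepam = 1.2, 1.5)
  # Control plasticity uses the same inverse learning rate the predictor
  # assumes; NMDA-receptor blockade slows plasticity twenty-fold but does
  # not abolish it.
  if (is.null(plasticity_lambda))
    plasticity_lambda <- if (condition == "apv") 51200 else 2560
  structure(list(n_electrodes = as.integer(n_electrodes),
                 group_fractions = group_fractions,
                 baseline_rate = baseline_rate,
                 gain = gain,
                 baseline_jitter_sd = baseline_jitter_sd,
                 gain_jitter_sd = gain_jitter_sd,
                 n_direct_inputs = as.integer(n_direct_inputs),
                 noise_dispersion = noise_dispersion,
                 trend_slope = trend_slope,
                 condition = condition,
                 plasticity_lambda = plasticity_lambda,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

# Implicit state prior of the latent network for each condition.
condition_prior_d1 <- function(condition) {
  switch(condition, bicuculline = 0.8, diazepam = 0.2, 0.5)
}

# Mixing fraction override for the mix conditions.
condition_mix_fraction <- function(condition, default) {
  switch(condition, mix0 = 0, mix50 = 0.5, default)
}

#' Generate a synthetic MEA recording
#'
#' Simulates the latent source-coding ensemble responses with the
#' canonical network (threshold factors set by the pharmacological
#' condition), assigns electrodes to source-preferring / no-preference
#' groups, and draws per-electrode per-trial spike counts as negative
#' binomial around \code{baseline + gain * latent + trend}. No-preference
#' electrodes are directly driven by a small random subset of stimulation
#' channels (the directly evoked component of real recordings) instead of
#' a latent ensemble. Per-electrode baselines and gains get lognormal
#' heterogeneity.
#'
#' @param design an \code{\link{experiment_design}} (its mixing fraction
#'   is overridden by \code{mix0} / \code{mix50} conditions).
#' @param cfg a \code{\link{synthetic_config}}.
#' @return object of class \code{raw_recording}: \code{counts}
#'   (\code{n_electrodes x T} integer matrix), \code{session},
#'   \code{trial}, \code{sources}, \code{stimuli} (the
#'   \code{stimulus_set}), \code{group} (true electrode assignment),
#'   \code{latent} (T x 2 latent ensemble responses), \code{network} (the
#'   latent \code{network_trajectory}), \code{cfg}, \code{design}.
#' @export
generate_recording <- function(design, cfg = synthetic_config()) {
  stopifnot(inherits(design, "experiment_design"),
            inherits(cfg, "synthetic_config"))
  design$mix_fraction <- condition_mix_fraction(cfg$condition,
                                                design$mix_fraction)
  stim <- generate_session_stimuli(design)
  d1 <- condition_prior_d1(cfg$condition)
  phi <- prior_threshold_factors(d1)
  net <- simulate_network_training(
    stim, phi,
    W_init = init_weights(design$n_inputs,
                          seed = spawn_seed(design$seed, 3L)),
    lambda_w = cfg$plasticity_lambda)
  latent <- net$x
  n_e <- cfg$n_electrodes
  n_t <- nrow(latent)
  set.seed(spawn_seed(cfg$seed, 4L))
  n_grp <- c(source1 = round(n_e * cfg$group_fractions[["source1"]]),
             source2 = round(n_e * cfg$group_fractions[["source2"]]))
  n_grp <- c(n_grp, none = n_e - sum(n_grp))
  group <- sample(rep(c("source1", "source2", "none"), times = n_grp))
  base_e <- cfg$baseline_rate * exp(stats::rnorm(n_e, 0, cfg$baseline_jitter_sd))
  gain_e <- cfg$gain * exp(stats::rnorm(n_e, 0, cfg$gain_jitter_sd))
  session_trend <- cfg$trend_slope * (stim$session - 1)
  drv <- matrix(NA_real_, n_e, n_t)
  drv[group == "source1", ] <- rep(latent[, 1], each = sum(group == "source1"))
  drv[group == "source2", ] <- rep(latent[, 2], each = sum(group == "source2"))
  for (e in which(group == "none")) {
    picks <- sample.int(design$n_inputs, min(cfg$n_direct_inputs,
                                             design$n_inputs))
    drv[e, ] <- rowMeans(stim$observations[, picks, drop = FALSE])
  }
  mu <- base_e + gain_e * drv                          # n_e x T
  mu <- sweep(mu, 2, session_trend, `+`)
  counts <- matrix(stats::rnbinom(length(mu), mu = as.vector(mu),
                                  size = cfg$noise_dispersion),
                   nrow = n_e)
  structure(list(counts = counts,
                 session = stim$session, trial = stim$trial,
                 sources = stim$sources, stimuli = stim,
                 group = group, latent = latent, network = net,
                 cfg = cfg, design = design),
            class = "raw_recording")
}

#' @export
print.raw_recording <- function(x, ...) {
  cat(sprintf(
    "raw_recording (%s): %d electrodes x %d trials, grand mean %.2f spikes/trial\n",
    x$cfg$condition, nrow(x$counts), ncol(x$counts), mean(x$counts)))
  invisible(x)
}

#' Classify electrodes by source preference
#'
#' Electrodes whose all-session mean response is not larger than 1
#' spike/trial are excluded. For the remainder, the preference statistic
#' is the all-session average of the per-session conditional mean
#' difference \code{E[r | s = (1,0)] - E[r | s = (0,1)]}: strictly above
#' +0.5 spikes/trial is source-1-preferring, strictly below -0.5
#' source-2-preferring, otherwise no preference (ties at exactly 0.5 are
#' no-preference).
#'
#' @param rec a \code{\link{generate_recording}} result, or a list with
#'   \code{counts}, \code{sources}, \code{session}.
#' @return object of class \code{electrode_classification}: data.frame
#'   with \code{electrode}, \code{label}, \code{preference_stat},
#'   \code{mean_rate}.
#' @export
classify_electrodes <- function(rec) {
  counts <- rec$counts
  s <- rec$sources
  session <- rec$session
  mean_rate <- rowMeans(counts)
  st <- joint_state_index(s[, 1], s[, 2])
  sessions <- unique(session)
  # Per-session E[r | (1,0)] - E[r | (0,1)], averaged across sessions.
  diffs <- matrix(NA_real_, nrow(counts), length(sessions))
  for (k in seq_along(sessions)) {
    idx10 <- which(session == sessions[k] & st == 2L)
    idx01 <- which(session == sessions[k] & st == 3L)
    if (length(idx10) && length(idx01))
      diffs[, k] <- rowMeans(counts[, idx10, drop = FALSE]) -
        rowMeans(counts[, idx01, drop = FALSE])
  }
  pref <- rowMeans(diffs, na.rm = TRUE)
  label <- ifelse(mean_rate <= 1, "excluded",
                  ifelse(pref > 0.5, "source1_preferring",
                         ifelse(pref < -0.5, "source2_preferring",
                                "no_preference")))
  structure(data.frame(electrode = seq_len(nrow(counts)),
                       label = label,
                       preference_stat = pref,
                       mean_rate = mean_rate),
            class = c("electrode_classification", "data.frame"))
}

#' Ensemble response series from a classified recording
#'
#' Averages counts within the source-1- and source-2-preferring groups per
#' trial, removes the slow trend (a linear fit of session-mean response
#' against session number, per ensemble; only the drift around the
#' all-session offset is subtracted, so condition-related shifts in mean
#' excitability survive), then normalises to (0, 1) by mapping the
#' OFF-state and ON-state evoked response levels — estimated as the means
#' of the lower and upper \code{ref_fraction} tails of the detrended
#' series — to 0 and 1. Tail means are robust cluster-centre estimates:
#' unlike extreme quantiles they are not biased by the count noise
#' variance growing with the mean. Values are clipped to
#' \code{[clip_eps, 1 - clip_eps]}; a degenerate (near-constant) series
#' maps to a flat 0.5.
#'
#' @param rec a \code{raw_recording}.
#' @param cls an \code{\link{classify_electrodes}} result.
#' @param ref_fraction tail fraction defining the OFF/ON reference levels.
#' @param clip_eps bound keeping responses inside the open unit interval.
#' @param fallback what to do when a preferring group is empty (as happens
#'   when no functional specialisation can emerge, e.g. under uniform 50\%
#'   mixing): \code{"error"} stops with advice to regenerate or adjust the
#'   configuration; \code{"sign_split"} splits the included electrodes by
#'   the sign of their preference statistic so downstream cost/free-energy
#'   analyses can still run (specificity then reflects chance).
#' @return object of class \code{ensemble_responses}: \code{x}
#'   (\code{T x 2} matrix), \code{session}, \code{trial},
#'   \code{n_electrodes} used per ensemble, \code{fallback_used} flag.
#' @export
ensemble_responses <- function(rec, cls, ref_fraction = 0.2,
                               clip_eps = 1e-3,
                               fallback = c("error", "sign_split")) {
  fallback <- match.arg(fallback)
  counts <- rec$counts
  session <- rec$session
  idx1 <- which(cls$label == "source1_preferring")
  idx2 <- which(cls$label == "source2_preferring")
  fallback_used <- FALSE
  if (length(idx1) == 0 || length(idx2) == 0) {
    if (fallback == "error")
      stop(paste("empty source-preferring ensemble; regenerate with a",
                 "different seed or adjust the synthetic configuration"))
    inc <- which(cls$label != "excluded")
    if (length(inc) < 2) stop("fewer than two included electrodes")
    stat <- cls$preference_stat[inc]
    pos <- stat > stats::median(stat)
    if (all(pos) || !any(pos)) pos <- seq_along(inc) <= length(inc) / 2
    idx1 <- inc[pos]
    idx2 <- inc[!pos]
    fallback_used <- TRUE
  }
  normalise <- function(y) {
    sm <- tapply(y, session, mean)
    s_id <- as.numeric(names(sm))
    fit <- stats::lm.fit(cbind(1, s_id), as.vector(sm))
    # Remove drift only: keep the all-session offset in place.
    y <- y - fit$coefficients[2] * (session - mean(s_id))
    lo <- stats::quantile(y, ref_fraction, names = FALSE)
    hi <- stats::quantile(y, 1 - ref_fraction, names = FALSE)
    level0 <- mean(y[y <= lo])
    level1 <- mean(y[y >= hi])
    if (level1 - level0 < 1e-9) return(rep(0.5, length(y)))
    clip_unit((y - level0) / (level1 - level0), clip_eps)
  }
  x <- cbind(x1 = normalise(colMeans(counts[idx1, , drop = FALSE])),
             x2 = normalise(colMeans(counts[idx2, , drop = FALSE])))
  structure(list(x = x, session = session, trial = rec$trial,
                 n_electrodes = c(length(idx1), length(idx2)),
                 fallback_used = fallback_used),
            class = "ensemble_responses")
}

#' @export
print.ensemble_responses <- function(x, ...) {
  cat(sprintf(
    "ensemble_responses: %d trials, %d + %d electrodes, mean x = (%.2f, %.2f)\n",
    nrow(x$x), x$n_electrodes[1], x$n_electrodes[2],
    mean(x$x[, 1]), mean(x$x[, 2])))
  invisible(x)
}

#' Response specificity to the preferred source
#'
#' For each session, the mean response on trials where the source is ON
#' minus the mean on OFF trials; reported as change from session 1 (the
#' ON/OFF difference already removes the per-session average response, so
#' slow trends cancel).
#'
#' @param x \code{T x 2} response matrix (or \code{ensemble_responses}).
#' @param sources binary \code{T x 2} true source matrix.
#' @param session session label per trial.
#' @param ensemble which response column to use (default 1).
#' @param source which source defines ON/OFF (default same as ensemble).
#' @return data.frame with \code{session}, \code{difference} (ON minus
#'   OFF) and \code{specificity} (difference minus its session-1 value).
#' @export
specificity_statistic <- function(x, sources, session = NULL, ensemble = 1L,
                                  source = ensemble) {
  if (inherits(x, "ensemble_responses")) {
    session <- x$session
    x <- x$x
  }
  if (is.null(session)) session <- rep(1L, nrow(x))
  sessions <- sort(unique(session))
  s_on <- sources[, source] == 1
  d <- vapply(sessions, function(k) {
    idx <- session == k
    on <- x[idx & s_on, ensemble]
    off <- x[idx & !s_on, ensemble]
    if (length(on) == 0 || length(off) == 0)
      stop("session lacks ON or OFF trials")
    mean(on) - mean(off)
  }, numeric(1))
  data.frame(session = sessions, difference = d, specificity = d - d[1])
}
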