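#' Dirichlet prior over the likelihood tensor
#'
#' Concentration parameters shaped like the mixing tensor
#' \code{[n_inputs, 2, 4]}: a near-flat prior of magnitude 1 per cell with
#' a small seeded jitter and, by default, a weak structured tilt.
#'
#' The tilt addresses two degeneracies of mean-field source separation.
#' With an exactly flat prior the updates are permutation-symmetric
#' between the two latent sources and provably never separate them; worse,
#' the fastest-growing unstable mode from a neutral initialisation is the
#' global-activity mode (both sources summed), a self-consistent local
#' free-energy minimum that does not separate the sources. The tilt
#' selects the separating basin and fixes the source labelling (latent 1
#' to the first half of the inputs): concentrations for the ON observation
#' are multiplied by \code{1 + tilt * p} with pattern \code{p = +1} in the
#' all-ON joint state, \code{-1} in the all-OFF state, and a left/right
#' contrast in the two single-source states (OFF cells get the
#' complementary factor). Its evidential mass (a fraction of a single
#' trial per cell) is negligible against the data, so learned likelihood
#' values come from the observations; the tilt only picks which of the
#' degenerate solutions is learned — the role played in vitro by the
#' pre-existing connectivity structure of the tissue.
#'
#' @param n_inputs number of inputs.
#' @param magnitude base concentration per cell (maps to the inverse
#'   learning rate of the network formulation).
#' @param jitter_sd standard deviation of the lognormal jitter.
#' @param structure_tilt relative strength of the basin-selecting tilt
#'   (0 disables it).
#' @param groups character vector assigning inputs to the \code{"left"} /
#'   \code{"right"} stimulus groups (default: first and second halves).
#' @param seed integer seed for the jitter stream.
#' @return array \code{[n_inputs, 2, 4]} of positive concentrations.
#' @export
dirichlet_prior <- function(n_inputs = 32L, magnitude = 1, jitter_sd = 0.01,
                            structure_tilt = 0.1,
                            groups = rep(c("left", "right"),
                                         each = n_inputs / 2),
                            seed = 1L) {
  set.seed(seed)
  a <- array(magnitude, dim = c(n_inputs, 2L, 4L),
             dimnames = list(NULL, c("on", "off"), .joint_labels))
  if (jitter_sd > 0)
    a <- a * exp(array(stats::rnorm(length(a), 0, jitter_sd), dim = dim(a)))
  if (structure_tilt > 0) {
    pat <- source_structure_pattern(n_inputs, groups)
    a[, 1, ] <- a[, 1, ] * (1 + structure_tilt * pat)
    a[, 2, ] <- a[, 2, ] * (1 - structure_tilt * pat)
  }
  a
}

# Qualitative ON-tilt pattern per (input, joint state), in [-1, 1]:
# all-ON state +1, all-OFF -1, single-source states a left/right contrast.
source_structure_pattern <- function(n_inputs, groups) {
  left <- groups == "left"
  pat <- matrix(0, n_inputs, 4)
  pat[, 1] <- 1
  pat[, 4] <- -1
  pat[, 2] <- ifelse(left, 1, -1)
  pat[, 3] <- ifelse(left, -1, 1)
  pat
}

#' Posterior expectation of the log likelihood tensor
#'
#' For Dirichlet beliefs with concentrations \code{a}, the expected log
#' likelihood is the digamma difference
#' \code{psi(a) - psi(a_on + a_off)}, evaluated cellwise.
#'
#' @param a concentration array \code{[n_inputs, 2, 4]}, all entries > 0.
#' @return array of the same shape (nats).
#' @export
expected_log_likelihood <- function(a) {
  if (any(a <= 0)) stop("Dirichlet concentrations must be positive")
  tot <- a[, 1, , drop = FALSE] + a[, 2, , drop = FALSE]
  lnA <- digamma(a)
  lnA[, 1, ] <- lnA[, 1, ] - digamma(tot[, 1, ])
  lnA[, 2, ] <- lnA[, 2, ] - digamma(tot[, 1, ])
  lnA
}

#' Posterior mean of the likelihood tensor
#'
#' @param a concentration array \code{[n_inputs, 2, 4]}.
#' @return array of posterior mean probabilities, normalised over the
#'   observation dimension.
#' @export
posterior_mean_A <- function(a) {
  tot <- a[, 1, ] + a[, 2, ]
  out <- a
  out[, 1, ] <- a[, 1, ] / tot
  out[, 2, ] <- a[, 2, ] / tot
  out
}

# Per-trial log evidence for each joint state:
# M[st] = sum_i o_i lnA[i,on,st] + (1 - o_i) lnA[i,off,st].
joint_log_evidence <- function(o, lnA) {
  as.vector(o %*% lnA[, 1, ] + (1 - o) %*% lnA[, 2, ])
}

#' Mean-field state posterior for one trial
#'
#' Computes the factorised posterior over the two sources by softmax of
#' the accumulated evidence, \code{s = softmax(lnA . o + ln D)} per
#' source, where each source's evidence is averaged over the other
#' source's current belief. The coupled per-source updates are iterated to
#' their fixed point (coordinate ascent). The iteration is initialised at
#' the marginals of the exact four-state joint posterior (cheap to
#' enumerate), so it converges to the factorised fixed point nearest the
#' exact posterior; when the exact joint posterior is itself a product of
#' marginals, the result equals it. Starting instead from an
#' uninformative belief would let the conjunction states' extreme
#' likelihoods dominate the first coordinate update and commit single
#' source states to the wrong corner on near-balanced observations.
#'
#' @param o binary observation vector (length \code{n_inputs}).
#' @param lnA expected log likelihood array from
#'   \code{\link{expected_log_likelihood}}.
#' @param ln_d matrix \code{2 x 2}: rows are sources, columns the log prior
#'   of the ON and OFF levels.
#' @param max_iter,tol fixed-point iteration controls.
#' @return list with \code{per_source} (2 x 2 matrix of posterior
#'   probabilities, rows sources, columns ON/OFF) and \code{joint}
#'   (length-4 vector over the joint states, the outer product of the
#'   marginals).
#' @export
state_posterior_update <- function(o, lnA, ln_d, max_iter = 32L,
                                   tol = 1e-10) {
  M <- joint_log_evidence(o, lnA)
  if (any(!is.finite(M)))
    stop("non-finite evidence in state posterior update")
  ln_d_joint <- c(ln_d[1, 1] + ln_d[2, 1], ln_d[1, 1] + ln_d[2, 2],
                  ln_d[1, 2] + ln_d[2, 1], ln_d[1, 2] + ln_d[2, 2])
  v <- M + ln_d_joint
  p_exact <- exp(v - max(v)); p_exact <- p_exact / sum(p_exact)
  q1 <- c(p_exact[1] + p_exact[2], p_exact[3] + p_exact[4])
  q2 <- c(p_exact[1] + p_exact[3], p_exact[2] + p_exact[4])
  softmax2 <- function(u) { e <- exp(u - max(u)); e / sum(e) }
  for (it in seq_len(max_iter)) {
    # State order (1,1),(1,0),(0,1),(0,0): source 1 ON mixes M[1], M[2].
    e1 <- c(M[1] * q2[1] + M[2] * q2[2], M[3] * q2[1] + M[4] * q2[2])
    q1_new <- softmax2(ln_d[1, ] + e1)
    e2 <- c(M[1] * q1_new[1] + M[3] * q1_new[2],
            M[2] * q1_new[1] + M[4] * q1_new[2])
    q2_new <- softmax2(ln_d[2, ] + e2)
    delta <- max(abs(q1_new - q1), abs(q2_new - q2))
    q1 <- q1_new; q2 <- q2_new
    if (delta < tol) break
  }
  per_source <- rbind(source1 = q1, source2 = q2)
  colnames(per_source) <- c("on", "off")
  list(per_source = per_source,
       joint = joint_from_marginals(q1[1], q2[1]))
}

#' Accumulate Dirichlet concentrations with one trial
#'
#' Adds the outer product of the observation indicator (ON/OFF) with the
#' joint state posterior; each trial adds total mass 1 per input.
#'
#' @param a concentration array.
#' @param o binary observation vector.
#' @param s_post posterior from \code{\link{state_posterior_update}} (or any
#'   list with a \code{joint} element).
#' @return updated concentration array.
#' @export
dirichlet_update <- function(a, o, s_post) {
  joint <- s_post$joint
  a[, 1, ] <- a[, 1, ] + outer(o, joint)
  a[, 2, ] <- a[, 2, ] + outer(1 - o, joint)
  if (any(a < 0)) stop("negative Dirichlet concentration")
  a
}

#' Variational free energy of a trial sequence
#'
#' Evaluates the state-dependent part of the free energy,
#' \code{F = sum_t s_t . (ln s_t - lnA . o_t - ln D)}, in nats. The
#' parameter-complexity term (of order \code{ln t}) is constant in the
#' states and omitted; reported differences between sessions are therefore
#' unaffected. Both observation levels (\code{o} and \code{1 - o}) enter the
#' accuracy term. Posterior entries of exactly zero follow the convention
#' \code{0 * log(0) = 0}.
#'
#' @param posteriors matrix \code{T x 4} of joint state posteriors (or a
#'   list of posteriors as returned by \code{\link{state_posterior_update}}).
#' @param stimuli binary observation matrix \code{T x n_inputs}.
#' @param lnA expected log likelihood array.
#' @param ln_d log state prior, \code{2 x 2} matrix as in
#'   \code{\link{state_posterior_update}}.
#' @return scalar free energy (nats); additive over trials.
#' @export
free_energy <- function(posteriors, stimuli, lnA, ln_d) {
  if (is.list(posteriors))
    posteriors <- do.call(rbind, lapply(posteriors, `[[`, "joint"))
  if (is.null(dim(stimuli))) stimuli <- matrix(stimuli, nrow = 1)
  if (is.null(dim(posteriors))) posteriors <- matrix(posteriors, nrow = 1)
  if (nrow(posteriors) != nrow(stimuli))
    stop("posteriors and stimuli must have the same number of trials")
  M <- stimuli %*% lnA[, 1, ] + (1 - stimuli) %*% lnA[, 2, ]   # T x 4
  ln_d_joint <- c(ln_d[1, 1] + ln_d[2, 1], ln_d[1, 1] + ln_d[2, 2],
                  ln_d[1, 2] + ln_d[2, 1], ln_d[1, 2] + ln_d[2, 2])
  ent <- rowSums(xlogx(posteriors))
  acc <- rowSums(posteriors * M)
  pri <- as.vector(posteriors %*% ln_d_joint)
  sum(ent - acc - pri)
}

#' Run the ideal variational Bayesian observer
#'
#' Sequential inference and learning over a stimulus sequence: for every
#' trial the state posterior is computed from the current expected log
#' likelihood and the state prior, then the Dirichlet concentrations are
#' incremented. The expected log likelihood is refreshed after every trial
#' by default (\code{schedule = "trial"}); \code{"session"} refreshes it
#' once per session, a faster approximation.
#'
#' @param stimuli a \code{stimulus_set} from
#'   \code{\link{generate_session_stimuli}}, or a binary matrix
#'   \code{T x n_inputs}.
#' @param prior a \code{\link{state_prior}} used by the observer (its
#'   implicit bias; may differ from the generative one).
#' @param a_init initial Dirichlet concentrations; default
#'   \code{\link{dirichlet_prior}} with the given seed.
#' @param schedule \code{"trial"} or \code{"session"} likelihood refresh.
#'   The session schedule holds the expected log likelihood fixed within
#'   each session (an adiabatic fast-inference / slow-learning split) and
#'   evaluates all of a session's state posteriors in vectorised form,
#'   which is much faster for multi-seed experiments.
#' @param session integer vector of session labels per trial (taken from
#'   \code{stimuli} when it is a \code{stimulus_set}).
#' @param seed seed for the default prior jitter.
#' @return object of class \code{observer_trajectory}: list with
#'   \code{posterior_on} (T x 2 matrix of per-source ON posteriors),
#'   \code{a} (final concentrations), \code{a_by_session} (list of
#'   end-of-session snapshots), \code{free_energy} (per-session, nats) and
#'   \code{session}.
#' @export
run_ideal_observer <- function(stimuli, prior = state_prior(),
                               a_init = NULL,
                               schedule = c("trial", "session"),
                               session = NULL, seed = 1L) {
  schedule <- match.arg(schedule)
  if (inherits(stimuli, "stimulus_set")) {
    session <- stimuli$session
    obs <- stimuli$observations
  } else {
    obs <- stimuli
    if (is.null(session)) session <- rep(1L, nrow(obs))
  }
  n_trials <- nrow(obs)
  n_inputs <- ncol(obs)
  if (is.null(a_init)) a_init <- dirichlet_prior(n_inputs, seed = seed)
  ln_d <- rbind(log(c(prior$d1[1], prior$d0[1])),
                log(c(prior$d1[2], prior$d0[2])))
  a <- a_init
  lnA <- expected_log_likelihood(a)
  posterior_on <- matrix(NA_real_, n_trials, 2,
                         dimnames = list(NULL, c("s1", "s2")))
  sessions <- unique(session)
  a_by_session <- vector("list", length(sessions))
  fe <- numeric(length(sessions))
  names(fe) <- names(a_by_session) <- as.character(sessions)
  joint_post <- matrix(NA_real_, n_trials, 4)
  if (schedule == "trial") {
    for (t in seq_len(n_trials)) {
      o <- obs[t, ]
      sp <- state_posterior_update(o, lnA, ln_d)
      posterior_on[t, ] <- sp$per_source[, "on"]
      joint_post[t, ] <- sp$joint
      a <- dirichlet_update(a, o, sp)
      lnA <- expected_log_likelihood(a)
      if (t == n_trials || session[t + 1] != session[t]) {
        k <- match(session[t], sessions)
        a_by_session[[k]] <- a
        idx <- which(session == session[t])
        fe[k] <- free_energy(joint_post[idx, , drop = FALSE],
                             obs[idx, , drop = FALSE], lnA, ln_d)
      }
    }
  } else {
    for (k in seq_along(sessions)) {
      idx <- which(session == sessions[k])
      O <- obs[idx, , drop = FALSE]
      q <- .batch_state_posteriors(O, lnA, ln_d)
      posterior_on[idx, ] <- q$per_source_on
      joint_post[idx, ] <- q$joint
      a[, 1, ] <- a[, 1, ] + crossprod(O, q$joint)
      a[, 2, ] <- a[, 2, ] + crossprod(1 - O, q$joint)
      fe[k] <- free_energy(q$joint, O, lnA, ln_d)
      lnA <- expected_log_likelihood(a)
      a_by_session[[k]] <- a
    }
  }
  structure(list(posterior_on = posterior_on,
                 a = a, a_init = a_init,
                 a_by_session = a_by_session,
                 free_energy = fe,
                 session = session,
                 prior = prior),
            class = "observer_trajectory")
}

# Vectorised mean-field state posteriors for a block of trials under a
# fixed expected log likelihood: exact four-state enumeration seeds the
# coordinate ascent, as in state_posterior_update.
.batch_state_posteriors <- function(O, lnA, ln_d, n_iter = 16L) {
  M <- O %*% lnA[, 1, ] + (1 - O) %*% lnA[, 2, ]        # T x 4
  ln_d_joint <- c(ln_d[1, 1] + ln_d[2, 1], ln_d[1, 1] + ln_d[2, 2],
                  ln_d[1, 2] + ln_d[2, 1], ln_d[1, 2] + ln_d[2, 2])
  V <- sweep(M, 2, ln_d_joint, `+`)
  V <- V - apply(V, 1, max)
  P <- exp(V); P <- P / rowSums(P)
  q1 <- P[, 1] + P[, 2]
  q2 <- P[, 1] + P[, 3]
  b1 <- ln_d[1, 1] - ln_d[1, 2]
  b2 <- ln_d[2, 1] - ln_d[2, 2]
  for (it in seq_len(n_iter)) {
    e1 <- (M[, 1] - M[, 3]) * q2 + (M[, 2] - M[, 4]) * (1 - q2)
    q1 <- 1 / (1 + exp(-(b1 + e1)))
    e2 <- (M[, 1] - M[, 2]) * q1 + (M[, 3] - M[, 4]) * (1 - q1)
    q2 <- 1 / (1 + exp(-(b2 + e2)))
  }
  list(per_source_on = cbind(q1, q2),
       joint = cbind(q1 * q2, q1 * (1 - q2), (1 - q1) * q2,
                     (1 - q1) * (1 - q2)))
}

#' @export
print.observer_trajectory <- function(x, ...) {
  cat(sprintf(
    "observer_trajectory: %d trials, %d sessions, final F[last session] = %.2f nats\n",
    nrow(x$posterior_on), length(x$free_energy),
    x$free_energy[length(x$free_energy)]))
  invisible(x)
}

#' Align recovered latent sources to the true sources
#'
#' Blind source separation recovers sources only up to a permutation of
#' labels. Given the observer's per-source posteriors and the true source
#' sequence, returns the label permutation maximising the total correlation
#' between posterior and truth.
#'
#' @param posterior_on matrix \code{T x 2} of per-source ON posteriors.
#' @param sources true binary source matrix \code{T x 2}.
#' @return integer vector of length 2: \code{perm[j]} is the latent index
#'   encoding true source \code{j}.
#' @export
align_sources <- function(posterior_on, sources) {
  cc <- suppressWarnings(stats::cor(posterior_on, sources))
  cc[!is.finite(cc)] <- 0
  if (sum(diag(cc)) >= cc[1, 2] + cc[2, 1]) c(1L, 2L) else c(2L, 1L)
}

#' Permute the source dimension of a likelihood-shaped array
#'
#' Swapping the two latent sources permutes the joint-state columns
#' (1,1),(1,0),(0,1),(0,0) to (1,1),(0,1),(1,0),(0,0).
#'
#' @param a array \code{[n_inputs, 2, 4]}.
#' @param perm permutation from \code{\link{align_sources}}.
#' @return array with the source roles permuted.
#' @export
permute_source_axes <- function(a, perm) {
  if (identical(perm, c(1L, 2L))) return(a)
  a[, , c(1L, 3L, 2L, 4L)]
}
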