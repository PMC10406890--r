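#' Run the full analysis pipeline
#'
#' Orchestrates one end-to-end experiment: generate stimuli, synthesise an
#' MEA recording, classify electrodes, extract ensemble responses, reverse
#' engineer the implicit generative model (threshold factors and per-session
#' effective connectivity), predict sessions beyond the initial window, and
#' evaluate the error metrics (posterior likelihood error, weight and
#' response prediction errors, empirical free energy change).
#'
#' @param config list (or path to a JSON/YAML file) with any of:
#'   \code{seed}, \code{condition}, \code{n_sessions},
#'   \code{trials_per_session}, \code{mix_fraction}, \code{d1_source1},
#'   \code{d1_source2}, \code{n_init_sessions}, \code{lambda_w},
#'   \code{n_electrodes}, \code{out_dir}. Unset keys take the package
#'   defaults.
#' @param write_outputs if \code{TRUE} (and \code{out_dir} is set), write
#'   stimuli, ensemble responses, metrics and a manifest under
#'   \code{out_dir}.
#' @return object of class \code{run_manifest}: list with \code{config},
#'   the key intermediate objects, a \code{metrics} data.frame (per
#'   session: A-error, weight prediction error, response error, F change)
#'   and \code{files} (paths written, possibly empty).
#' @export
run_full_pipeline <- function(config = list(), write_outputs = FALSE) {
  if (is.character(config)) {
    config <- if (grepl("\\.ya?ml$", config)) yaml::read_yaml(config)
              else jsonlite::read_json(config, simplifyVector = TRUE)
  }
  defaults <- list(seed = 1L, condition = "control", n_sessions = 100L,
                   trials_per_session = 256L, mix_fraction = 0.25,
                   d1_source1 = 0.5, d1_source2 = 0.5,
                   n_init_sessions = 10L, lambda_w = 2560,
                   n_electrodes = 44L, out_dir = NULL)
  cfg <- utils::modifyList(defaults, config)
  design <- experiment_design(n_sessions = cfg$n_sessions,
                              trials_per_session = cfg$trials_per_session,
                              mix_fraction = cfg$mix_fraction,
                              prior = state_prior(cfg$d1_source1,
                                                  cfg$d1_source2),
                              seed = cfg$seed)
  syn <- synthetic_config(n_electrodes = cfg$n_electrodes,
                          condition = cfg$condition, seed = cfg$seed)
  rec <- generate_recording(design, syn)
  cls <- classify_electrodes(rec)
  ens <- ensemble_responses(rec, cls, fallback = "sign_split")
  o <- rec$stimuli$observations
  session <- ens$session
  phi <- estimate_threshold_factors(ens, n_init_sessions = cfg$n_init_sessions)
  W_est <- estimate_effective_connectivity(ens, o)
  fe <- empirical_free_energy(ens, o, W_est, phi)
  A_ideal <- ideal_marginal_likelihood(rec$stimuli$A, design$prior)
  a_err <- t(vapply(W_est, function(W) {
    posterior_A_error(weights_to_posterior_A(W), A_ideal)
  }, numeric(4)))
  pred <- predict_trajectory(ens, o, n_init_sessions = cfg$n_init_sessions,
                             lambda_w = cfg$lambda_w)
  w_err <- vapply(seq_along(W_est), function(k) {
    weight_prediction_error(pred$W_by_session[[k]], W_est[[k]])
  }, numeric(1))
  resp <- response_prediction_error(ens$x, pred$x_pred, session,
                                    cor_window = utils::tail(sort(unique(session)), 10))
  spec1 <- specificity_statistic(ens, rec$sources, ensemble = 1L)
  spec2 <- specificity_statistic(ens, rec$sources, ensemble = 2L)
  metrics <- data.frame(session = fe$session,
                        A_error = rowMeans(a_err),
                        w_pred_error = w_err,
                        F_change = fe$F_change,
                        specificity = (spec1$specificity +
                                         spec2$specificity) / 2,
                        source_diff = (spec1$difference +
                                         spec2$difference) / 2)
  metrics <- merge(metrics, resp$per_session, by = "session", all.x = TRUE)
  manifest <- structure(list(config = cfg,
                             recording = rec,
                             classification = cls,
                             responses = ens,
                             phi = phi,
                             W_by_session = W_est,
                             prediction = pred,
                             metrics = metrics,
                             correlation = resp[grep("^correlation",
                                                     names(resp))],
                             files = character(0)),
                        class = "run_manifest")
  if (write_outputs && !is.null(cfg$out_dir)) {
    manifest$files <- write_manifest_outputs(manifest, cfg$out_dir)
  }
  manifest
}

#' @export
print.run_manifest <- function(x, ...) {
  m <- x$metrics
  last <- m[nrow(m), ]
  cat(sprintf("run_manifest (%s, seed %d): %d sessions\n",
              x$config$condition, x$config$seed, nrow(m)))
  cat(sprintf(
    "  session %d: A_error %.3f | w_pred_error %.4f | err %.4f | dF %.1f nats\n",
    last$session, last$A_error, last$w_pred_error, last$err, last$F_change))
  invisible(x)
}

# Write the plain-text outputs of a pipeline run; returns the paths.
write_manifest_outputs <- function(manifest, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- manifest$config
  paths <- c(
    design = file.path(out_dir, "design.json"),
    stimuli = file.path(out_dir, "stimuli.csv"),
    responses = file.path(out_dir, "ensemble_responses.csv"),
    classification = file.path(out_dir, "classification.csv"),
    metrics = file.path(out_dir, "metrics.csv"),
    model = file.path(out_dir, "reconstructed_model.json"),
    manifest = file.path(out_dir, "manifest.json"))
  write_design(manifest$recording$design, paths[["design"]])
  write_stimuli(manifest$recording$stimuli, paths[["stimuli"]])
  utils::write.csv(data.frame(session = manifest$responses$session,
                              trial = manifest$responses$trial,
                              manifest$responses$x),
                   paths[["responses"]], row.names = FALSE)
  utils::write.csv(manifest$classification, paths[["classification"]],
                   row.names = FALSE)
  utils::write.csv(manifest$metrics, paths[["metrics"]], row.names = FALSE)
  W_last <- manifest$W_by_session[[length(manifest$W_by_session)]]
  jsonlite::write_json(
    list(phi1 = manifest$phi$phi1, phi0 = manifest$phi$phi0,
         d_hat = manifest$phi$d_hat,
         W1_final = W_last$W1, W0_final = W_last$W0),
    paths[["model"]], auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(
    list(config = cfg[setdiff(names(cfg), "out_dir")],
         files = as.list(paths[setdiff(names(paths), "manifest")]),
         summary = list(
           final_A_error = manifest$metrics$A_error[nrow(manifest$metrics)],
           final_w_pred_error =
             manifest$metrics$w_pred_error[nrow(manifest$metrics)],
           final_F_change =
             manifest$metrics$F_change[nrow(manifest$metrics)])),
    paths[["manifest"]], auto_unbox = TRUE, digits = NA)
  paths
}

#' Compare metrics across experimental conditions
#'
#' Rank-based comparison (two-sided Mann-Whitney U test via
#' \code{\link[stats]{wilcox.test}}) of a per-run summary metric between
#' two groups of pipeline runs, e.g. control versus drug condition.
#'
#' @param manifests_a,manifests_b lists of \code{run_manifest} objects (or
#'   numeric vectors of the summary metric itself).
#' @param metric one of \code{"specificity"}, \code{"A_error"},
#'   \code{"w_pred_error"}, \code{"F_change"}; the session-100 (final)
#'   value per run is compared.
#' @return data.frame with group medians, the rank-test p-value and the
#'   direction of the difference.
#' @export
compare_conditions <- function(manifests_a, manifests_b,
                               metric = "specificity") {
  pull <- function(ms) {
    if (is.numeric(ms)) return(ms)
    vapply(ms, function(m) {
      v <- m$metrics[[metric]]
      v[length(v)]
    }, numeric(1))
  }
  a <- pull(manifests_a); b <- pull(manifests_b)
  wt <- stats::wilcox.test(a, b, exact = FALSE)
  data.frame(metric = metric,
             median_a = stats::median(a), median_b = stats::median(b),
             p_value = wt$p.value,
             direction = ifelse(stats::median(a) > stats::median(b),
                                "a > b", "a <= b"))
}
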