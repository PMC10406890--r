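#' Predict responses and plasticity from an initial window
#'
#' Implements prediction under the free-energy principle: threshold
#' factors and initial connectivity are estimated from the first
#' \code{n_init_sessions} of empirical responses; thereafter the model
#' evolves closed-loop, with no access to later empirical data. Each
#' predicted session computes fixed-point responses
#' \code{x_p = sig(W_p o + h_p)} with
#' \code{h_p = rowSums(log(1 - sig(W1_p))) - rowSums(log(1 - sig(W0_p))) + phi1 - phi0},
#' then updates the predicted weights to the plasticity fixed point of
#' cumulative predicted-response statistics, seeded with evidential mass
#' \code{lambda_w} at the initial estimate (the parameter-prior strength /
#' inverse learning rate).
#'
#' @param x empirical ensemble responses (\code{T x 2} matrix or
#'   \code{ensemble_responses}); only the initial window is consulted.
#' @param o binary stimulus matrix \code{T x n_inputs} for all sessions.
#' @param session session label per trial.
#' @param n_init_sessions length of the initial window (default 10).
#' @param lambda_w inverse learning rate: evidential mass of the initial
#'   estimate (default 2560, the weight of a 10-session x 256-trial
#'   window).
#' @param clip_eps ratio clipping for weight fixed points.
#' @param phi optional \code{\link{threshold_factors}} overriding the
#'   window estimate (e.g. for sensitivity analyses of threshold
#'   mismatch).
#' @return object of class \code{predicted_trajectory}: \code{x_pred}
#'   (T x 2, \code{NA} for the initial window), \code{W_by_session} (list
#'   over all sessions; initial-window entries hold the initial estimate),
#'   \code{phi}, \code{W_init}, \code{session}, \code{n_init_sessions}.
#' @export
predict_trajectory <- function(x, o, session = NULL, n_init_sessions = 10L,
                               lambda_w = 2560, clip_eps = 1e-3,
                               phi = NULL) {
  if (inherits(x, "ensemble_responses")) {
    session <- x$session
    x <- x$x
  }
  if (is.null(session)) stop("session labels are required")
  stopifnot(n_init_sessions >= 1, lambda_w > 0, nrow(x) == nrow(o))
  sessions <- sort(unique(session))
  if (length(sessions) <= n_init_sessions)
    stop("need more sessions than the initial window")
  init_sessions <- sessions[seq_len(n_init_sessions)]
  init_idx <- session %in% init_sessions
  if (is.null(phi))
    phi <- estimate_threshold_factors(x, session, n_init_sessions)
  W_init <- weights_fixed_point(
    sufficient_stats(x[init_idx, , drop = FALSE],
                     o[init_idx, , drop = FALSE]),
    clip_eps)
  # Cumulative predicted-response counts, anchored at the initial estimate.
  num1 <- lambda_w * sig(W_init$W1)
  num0 <- lambda_w * sig(W_init$W0)
  den1 <- rep(lambda_w, 2)
  den0 <- rep(lambda_w, 2)
  W_p <- W_init
  x_pred <- matrix(NA_real_, nrow(x), 2,
                   dimnames = list(NULL, c("x1", "x2")))
  W_by_session <- vector("list", length(sessions))
  names(W_by_session) <- as.character(sessions)
  for (k in seq_along(sessions)) {
    if (k <= n_init_sessions) {
      W_by_session[[k]] <- W_init
      next
    }
    idx <- which(session == sessions[k])
    O <- o[idx, , drop = FALSE]
    X <- response_fixed_point(O, W_p, phi)
    x_pred[idx, ] <- X
    num1 <- num1 + crossprod(X, O)
    num0 <- num0 + crossprod(1 - X, O)
    den1 <- den1 + colSums(X)
    den0 <- den0 + colSums(1 - X)
    r1 <- clip_unit(num1 / den1, clip_eps)
    r0 <- clip_unit(num0 / den0, clip_eps)
    W_p <- synaptic_weights(sig_inv(r1), sig_inv(r0))
    W_by_session[[k]] <- W_p
  }
  structure(list(x_pred = x_pred, W_by_session = W_by_session,
                 phi = phi, W_init = W_init, session = session,
                 n_init_sessions = n_init_sessions, lambda_w = lambda_w),
            class = "predicted_trajectory")
}

#' @export
print.predicted_trajectory <- function(x, ...) {
  cat(sprintf(
    "predicted_trajectory: %d sessions predicted from the first %d\n",
    length(x$W_by_session) - x$n_init_sessions, x$n_init_sessions))
  invisible(x)
}

#' Normalised weight prediction error
#'
#' Squared error between predicted and estimated weights in sigmoid space,
#' divided by the squared Frobenius norm of the estimated
#' \code{(sig(W1), sig(W0))} block.
#'
#' @param W_pred,W_est \code{\link{synaptic_weights}} objects.
#' @return scalar error fraction (multiply by 100 for percent).
#' @export
weight_prediction_error <- function(W_pred, W_est) {
  est <- cbind(sig(W_est$W1), sig(W_est$W0))
  prd <- cbind(sig(W_pred$W1), sig(W_pred$W0))
  n2 <- sum(est^2)
  if (n2 == 0) stop("zero-norm estimated weights")
  sum((prd - est)^2) / n2
}

#' Response prediction error per session
#'
#' Half the mean squared Euclidean deviation between observed and
#' predicted responses, \code{err = E[|x - x_p|^2] / 2}, per session.
#' Optionally also returns the Pearson correlation between observed and
#' predicted responses over a late window, both pooled over trials and on
#' per-session means.
#'
#' @param x observed \code{T x 2} responses.
#' @param x_pred predicted responses (same shape; \code{NA} rows are
#'   skipped).
#' @param session session label per trial.
#' @param cor_window optional session labels over which to compute
#'   observed/predicted correlations (e.g. \code{91:100}).
#' @return list with \code{per_session} (data.frame session, err) and,
#'   when requested, \code{correlation_pooled} and
#'   \code{correlation_session_means}.
#' @export
response_prediction_error <- function(x, x_pred, session,
                                      cor_window = NULL) {
  if (nrow(x) != nrow(x_pred)) stop("trial counts differ")
  ok <- stats::complete.cases(x_pred)
  sessions <- sort(unique(session[ok]))
  err <- vapply(sessions, function(s) {
    idx <- which(session == s & ok)
    mean(rowSums((x[idx, , drop = FALSE] -
                    x_pred[idx, , drop = FALSE])^2)) / 2
  }, numeric(1))
  out <- list(per_session = data.frame(session = sessions, err = err))
  if (!is.null(cor_window)) {
    idx <- which(session %in% cor_window & ok)
    out$correlation_pooled <-
      stats::cor(as.vector(x[idx, ]), as.vector(x_pred[idx, ]))
    sm_obs <- as.vector(as.matrix(
      stats::aggregate(x[idx, ], list(session[idx]), mean)[, -1]))
    sm_prd <- as.vector(as.matrix(
      stats::aggregate(x_pred[idx, ], list(session[idx]), mean)[, -1]))
    out$correlation_session_means <-
      if (stats::sd(sm_obs) == 0 || stats::sd(sm_prd) == 0) NA_real_
      else stats::cor(sm_obs, sm_prd)
  }
  out
}

#' Proportion of responses predicted
#'
#' Complement of the response prediction error relative to its worst case
#' on the unit box (\code{err_max = 0.5}): \code{1 - err / 0.5}. A value of
#' 0.8 corresponds to predicting 80\% of the responses.
#'
#' @param err response prediction error (from
#'   \code{\link{response_prediction_error}}).
#' @return fraction in [0, 1] (clamped below at 0).
#' @export
prediction_accuracy <- function(err) pmax(0, 1 - err / 0.5)
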