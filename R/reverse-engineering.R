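#' Estimate threshold factors from ensemble responses
#'
#' The threshold factors are the log mean responses over an initial window:
#' \code{phi1 = log(<x>)}, \code{phi0 = log(<1 - x>)}. Because the OFF
#' level is defined as one minus the response, the recovered implicit prior
#' expectations \code{exp(phi1) + exp(phi0)} sum to 1 exactly. The default
#' window is the first 10 sessions, over which the threshold is assumed
#' stationary.
#'
#' @param x \code{T x 2} ensemble response matrix with entries in (0, 1),
#'   or an \code{ensemble_responses} object.
#' @param session session label per trial (taken from \code{x} when it is
#'   an \code{ensemble_responses} object).
#' @param n_init_sessions number of initial sessions to average over.
#' @return a \code{\link{threshold_factors}} object with an added
#'   \code{d_hat} field: the implicit state prior \code{exp(phi1)} per
#'   ensemble.
#' @export
estimate_threshold_factors <- function(x, session = NULL,
                                       n_init_sessions = 10L) {
  if (inherits(x, "ensemble_responses")) {
    session <- x$session
    x <- x$x
  }
  stopifnot(n_init_sessions >= 1)
  if (is.null(session)) session <- rep(1L, nrow(x))
  keep <- session <= sort(unique(session))[min(n_init_sessions,
                                               length(unique(session)))]
  mx <- colMeans(x[keep, , drop = FALSE])
  if (any(mx <= 0) || any(mx >= 1))
    stop("degenerate ensemble: mean response outside (0, 1)")
  phi <- threshold_factors(log(mx), log(1 - mx))
  phi$d_hat <- mx
  phi
}

#' Estimate effective synaptic connectivity per session
#'
#' Applies the plasticity fixed point to cumulative sufficient statistics
#' from trial 1 through the end of each session, yielding one
#' \code{\link{synaptic_weights}} estimate per session (the model-based
#' effective connectivity of the recorded network).
#'
#' @param x \code{T x 2} ensemble responses in (0, 1), or an
#'   \code{ensemble_responses} object.
#' @param o binary \code{T x n_inputs} stimulus matrix.
#' @param session session label per trial.
#' @param upto_session estimate only through this session (default all).
#' @param clip_eps ratio clipping (see \code{\link{weights_fixed_point}}).
#' @return list of \code{synaptic_weights}, one per session (names are the
#'   session labels).
#' @export
estimate_effective_connectivity <- function(x, o, session = NULL,
                                            upto_session = NULL,
                                            clip_eps = 1e-3) {
  if (inherits(x, "ensemble_responses")) {
    session <- x$session
    x <- x$x
  }
  if (is.null(session)) session <- rep(1L, nrow(x))
  stopifnot(nrow(x) == nrow(o))
  sessions <- sort(unique(session))
  if (!is.null(upto_session)) sessions <- sessions[sessions <= upto_session]
  acc <- NULL
  out <- vector("list", length(sessions))
  names(out) <- as.character(sessions)
  for (k in seq_along(sessions)) {
    idx <- which(session == sessions[k])
    acc <- .accumulate_stats(acc, x[idx, , drop = FALSE],
                             o[idx, , drop = FALSE])
    out[[k]] <- weights_fixed_point(.stats_from_sums(acc), clip_eps)
  }
  out
}

#' Map synaptic weights to the posterior likelihood matrix
#'
#' Under the network / variational-Bayes equivalence the sigmoid of the
#' weights encodes the posterior expectation of the likelihood: row
#' \code{e} of \code{sig(W1)} is the believed probability of each input
#' being ON given source \code{e} ON, and \code{sig(W0)} given source
#' \code{e} OFF. The OFF-observation blocks are the complements.
#'
#' @param W a \code{\link{synaptic_weights}} object.
#' @return object of class \code{posterior_likelihood}: list of
#'   \code{2 x n_inputs} matrices \code{A1_on} (= sig(W1)), \code{A0_on}
#'   (= sig(W0)), \code{A1_off}, \code{A0_off}.
#' @export
weights_to_posterior_A <- function(W) {
  A1 <- sig(W$W1); A0 <- sig(W$W0)
  structure(list(A1_on = A1, A0_on = A0,
                 A1_off = 1 - A1, A0_off = 1 - A0),
            class = "posterior_likelihood")
}

#' Ideal marginal likelihood implied by the generative process
#'
#' The ensemble-level counterpart of the mixing tensor: the probability of
#' each input being ON conditioned on one source being ON (or OFF),
#' marginalising the other source under its prior. This is the target the
#' estimated \code{sig(W1)} / \code{sig(W0)} blocks converge to when the
#' network separates the sources.
#'
#' @param A a \code{\link{build_mixing_matrix}} tensor.
#' @param prior the generative \code{\link{state_prior}}.
#' @return list with \code{A1_on}, \code{A0_on} (\code{2 x n_inputs}),
#'   rows = conditioning source.
#' @export
ideal_marginal_likelihood <- function(A, prior = state_prior()) {
  n <- dim(A)[1]
  on1 <- prior$d1[1]; on2 <- prior$d1[2]
  # P(o=1 | s1 = 1) = E_{s2}[A_on(1, s2)], states (1,1)=1, (1,0)=2 etc.
  A1 <- rbind(on2 * A[, 1, 1] + (1 - on2) * A[, 1, 2],
              on1 * A[, 1, 1] + (1 - on1) * A[, 1, 3])
  A0 <- rbind(on2 * A[, 1, 3] + (1 - on2) * A[, 1, 4],
              on1 * A[, 1, 2] + (1 - on1) * A[, 1, 4])
  list(A1_on = A1, A0_on = A0)
}

#' Normalised error between posterior likelihood matrices
#'
#' Squared error between an estimated and a reference likelihood block,
#' divided by the squared amplitude of the reference, computed per column
#' of the stacked \code{(A1; A0)} block matrix (each column is the
#' likelihood vector of one conditioning source level, length
#' \code{n_inputs}).
#'
#' @param A_hat,A_ref lists with \code{A1_on} and \code{A0_on} matrices
#'   (\code{2 x n_inputs}), e.g. from \code{\link{weights_to_posterior_A}}
#'   and \code{\link{ideal_marginal_likelihood}}.
#' @return named numeric vector of length 4: normalised error for (source1
#'   ON, source2 ON, source1 OFF, source2 OFF) columns.
#' @export
posterior_A_error <- function(A_hat, A_ref) {
  block_err <- function(est, ref, e) {
    d2 <- sum((est[e, ] - ref[e, ])^2)
    n2 <- sum(ref[e, ]^2)
    if (n2 == 0) stop("zero-norm reference column")
    d2 / n2
  }
  c(s1_on = block_err(A_hat$A1_on, A_ref$A1_on, 1),
    s2_on = block_err(A_hat$A1_on, A_ref$A1_on, 2),
    s1_off = block_err(A_hat$A0_on, A_ref$A0_on, 1),
    s2_off = block_err(A_hat$A0_on, A_ref$A0_on, 2))
}

#' Empirical variational free energy per session
#'
#' Substitutes observed ensemble responses and the per-session estimated
#' connectivity into the network cost function, giving the empirical free
#' energy of each session; reported alongside as change from session 1.
#'
#' @param x \code{T x 2} responses (or \code{ensemble_responses}).
#' @param o binary stimulus matrix.
#' @param W_by_session list of per-session \code{synaptic_weights} (e.g.
#'   from \code{\link{estimate_effective_connectivity}}).
#' @param phi \code{\link{threshold_factors}}.
#' @param session session label per trial.
#' @return data.frame with columns \code{session}, \code{F} (nats) and
#'   \code{F_change} (F minus session-1 F).
#' @export
empirical_free_energy <- function(x, o, W_by_session, phi, session = NULL) {
  if (inherits(x, "ensemble_responses")) {
    session <- x$session
    x <- x$x
  }
  if (is.null(session)) session <- rep(1L, nrow(x))
  sessions <- sort(unique(session))
  sessions <- sessions[seq_len(min(length(sessions), length(W_by_session)))]
  f <- vapply(seq_along(sessions), function(k) {
    idx <- which(session == sessions[k])
    cost_function(x[idx, , drop = FALSE], o[idx, , drop = FALSE],
                  W_by_session[[k]], phi)
  }, numeric(1))
  data.frame(session = sessions, F = f, F_change = f - f[1])
}

#' Free energy landscape over a two-coordinate weight projection
#'
#' Projects the high-dimensional weight space onto two scalar coordinates —
#' by default the mean effective weight (\code{W1 - W0}) from left-group
#' inputs to ensemble 1 and from right-group inputs to ensemble 1 — and
#' evaluates, at each grid node, the cost of the fixed-point responses
#' under the modified weights (free energy minimised over responses). The
#' remaining entries are held at \code{W_base}.
#'
#' @param phi \code{\link{threshold_factors}} (estimated from the initial
#'   window).
#' @param o binary stimulus matrix used to evaluate the landscape.
#' @param W_base \code{\link{synaptic_weights}} supplying the non-varied
#'   entries.
#' @param coord1,coord2 numeric grid vectors for the two coordinates.
#' @param groups character vector of input group labels (\code{"left"} /
#'   \code{"right"}), e.g. the \code{group} attribute of the mixing tensor.
#' @return data.frame with \code{coord1}, \code{coord2} and \code{F}
#'   (nats); class \code{fe_landscape} with the grid attributes attached.
#' @export
landscape_projection <- function(phi, o, W_base, coord1, coord2,
                                 groups = rep(c("left", "right"),
                                              each = ncol(W_base$W1) / 2)) {
  if (length(coord1) == 0 || length(coord2) == 0)
    stop("empty landscape grid")
  left <- groups == "left"
  right <- groups == "right"
  eval_node <- function(c1, c2) {
    W <- W_base
    # Shift the effective drive of ensemble 1 by adjusting W1; the
    # projection coordinate is the mean effective weight per group.
    w_eff <- W$W1 - W$W0
    W$W1[1, left] <- W$W1[1, left] + (c1 - mean(w_eff[1, left]))
    W$W1[1, right] <- W$W1[1, right] + (c2 - mean(w_eff[1, right]))
    X <- response_fixed_point(o, W, phi)
    cost_function(X, o, W, phi)
  }
  grid <- expand.grid(coord1 = coord1, coord2 = coord2)
  grid$F <- mapply(eval_node, grid$coord1, grid$coord2)
  structure(grid, class = c("fe_landscape", "data.frame"))
}

#' Project a weight trajectory onto landscape coordinates
#'
#' @param W_by_session list of per-session \code{synaptic_weights}.
#' @param o binary stimulus matrix (one reference session is enough).
#' @param phi \code{\link{threshold_factors}}.
#' @param groups input group labels as in
#'   \code{\link{landscape_projection}}.
#' @return data.frame with per-session \code{coord1}, \code{coord2} (mean
#'   effective left/right-group weights onto ensemble 1) and \code{F}: the
#'   cost of the fixed-point responses under that session's weights.
#' @export
project_weight_trajectory <- function(W_by_session, o, phi,
                                      groups = rep(c("left", "right"),
                                                   each = ncol(W_by_session[[1]]$W1) / 2)) {
  left <- groups == "left"
  right <- groups == "right"
  rows <- lapply(seq_along(W_by_session), function(k) {
    W <- W_by_session[[k]]
    w_eff <- W$W1 - W$W0
    X <- response_fixed_point(o, W, phi)
    data.frame(session = k,
               coord1 = mean(w_eff[1, left]),
               coord2 = mean(w_eff[1, right]),
               F = cost_function(X, o, W, phi))
  })
  do.call(rbind, rows)
}
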