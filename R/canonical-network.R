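#' Synaptic weight container
#'
#' Excitatory (\code{W1}) and inhibitory (\code{W0}) strengths, each a
#' \code{2 x n_inputs} matrix (two neural ensembles). The effective weight
#' entering the response dynamics is \code{W = W1 - W0}; in sigmoid space,
#' \code{sig(W1)} and \code{sig(W0)} encode the posterior likelihood of an
#' input being ON given the corresponding source ON / OFF.
#'
#' @param W1,W0 numeric matrices \code{2 x n_inputs}.
#' @return object of class \code{synaptic_weights}.
#' @export
synaptic_weights <- function(W1, W0) {
  stopifnot(is.matrix(W1), is.matrix(W0), all(dim(W1) == dim(W0)),
            nrow(W1) == 2, all(is.finite(W1)), all(is.finite(W0)))
  structure(list(W1 = W1, W0 = W0), class = "synaptic_weights")
}

#' @export
print.synaptic_weights <- function(x, ...) {
  cat(sprintf("synaptic_weights: 2 ensembles x %d inputs\n", ncol(x$W1)))
  cat(sprintf("  mean sig(W1) = %.3f, mean sig(W0) = %.3f\n",
              mean(sig(x$W1)), mean(sig(x$W0))))
  invisible(x)
}

#' Random near-zero initial weights
#'
#' Synaptic strengths are initialised as i.i.d. Gaussian values close to
#' zero plus, by default, a weak structured tilt: a small excitatory bias
#' with a left/right contrast aligning ensemble 1 with the left input
#' group and ensemble 2 with the right group. The tilt plays the role of
#' the pre-existing connectivity structure of real tissue: from a fully
#' neutral initialisation the fastest-growing mode of the
#' Hebbian/homeostatic dynamics is the (possibly sign-inverted)
#' global-activity mode, a non-separating local optimum of the cost, and
#' which basin a network falls into is decided by its initial
#' asymmetries. The excitatory component selects upright (stimulation
#' increases firing) coding; the contrast selects the source labelling.
#' The amplitude is small in sigmoid space (about 1.5 percentage points
#' per unit tilt of 0.03 on each weight), so the learned weights are
#' shaped by the data.
#'
#' @param n_inputs number of inputs.
#' @param sigma standard deviation of the random component.
#' @param structure_tilt logit-space amplitude of the excitatory/contrast
#'   tilt (0 disables it).
#' @param groups input group labels (\code{"left"} / \code{"right"}).
#' @param seed integer seed.
#' @return a \code{\link{synaptic_weights}} object.
#' @export
init_weights <- function(n_inputs = 32L, sigma = 0.01,
                         structure_tilt = 0.03,
                         groups = rep(c("left", "right"),
                                      each = n_inputs / 2),
                         seed = 1L) {
  set.seed(seed)
  contrast <- ifelse(groups == "left", 1, -1)
  # Ensemble 1 tilts toward left-group inputs, ensemble 2 toward right.
  tilt <- structure_tilt * rbind(1 + contrast, 1 - contrast)
  synaptic_weights(
    W1 = matrix(stats::rnorm(2 * n_inputs, 0, sigma), 2, n_inputs) + tilt,
    W0 = matrix(stats::rnorm(2 * n_inputs, 0, sigma), 2, n_inputs) - tilt)
}

#' Threshold factors
#'
#' The constant components \code{phi1}, \code{phi0} of the firing
#' thresholds (one entry per ensemble, nats). Under the equivalence with
#' variational Bayes they encode the log state prior, \code{phi = ln D}.
#'
#' @param phi1,phi0 numeric length-2 vectors.
#' @return object of class \code{threshold_factors}.
#' @export
threshold_factors <- function(phi1, phi0) {
  stopifnot(length(phi1) == 2, length(phi0) == 2,
            all(is.finite(phi1)), all(is.finite(phi0)))
  structure(list(phi1 = phi1, phi0 = phi0), class = "threshold_factors")
}

#' Threshold factors encoding a given state prior
#'
#' @param d1 ON prior expectation applied to both ensembles (or length-2
#'   vector).
#' @return \code{\link{threshold_factors}} with \code{phi1 = log(d1)},
#'   \code{phi0 = log(1 - d1)}.
#' @export
prior_threshold_factors <- function(d1 = 0.5) {
  d1 <- rep_len(d1, 2)
  threshold_factors(log(d1), log(1 - d1))
}

#' Firing thresholds from weights and threshold factors
#'
#' \code{h_l = rowSums(log(1 - sig(W_l))) + phi_l} for l = 1, 0; the
#' effective threshold is \code{h = h1 - h0}.
#'
#' @param W a \code{\link{synaptic_weights}} object.
#' @param phi a \code{\link{threshold_factors}} object.
#' @return list with \code{h1}, \code{h0} and \code{h} (length-2 vectors).
#' @export
threshold_from_weights <- function(W, phi) {
  h1 <- rowSums(log(1 - sig(W$W1))) + phi$phi1
  h0 <- rowSums(log(1 - sig(W$W0))) + phi$phi0
  list(h1 = h1, h0 = h0, h = h1 - h0)
}

#' Fixed-point response of the canonical network
#'
#' The equilibrium of the leaky rate dynamics is the sigmoid of the net
#' input, \code{x = sig(W o + h)} with \code{W = W1 - W0}.
#'
#' @param o binary observation vector, or a \code{T x n_inputs} matrix for
#'   a whole block of trials.
#' @param W a \code{\link{synaptic_weights}} object.
#' @param phi a \code{\link{threshold_factors}} object.
#' @return numeric response: length-2 vector for a single trial, or a
#'   \code{T x 2} matrix. Responses are kept strictly inside (0, 1) (a
#'   saturated sigmoid would otherwise round to exactly 0 or 1 in double
#'   precision, making the leak term infinite).
#' @export
response_fixed_point <- function(o, W, phi) {
  h <- threshold_from_weights(W, phi)$h
  Wd <- W$W1 - W$W0
  if (is.matrix(o)) {
    x <- clip_unit(t(sig(Wd %*% t(o) + h)), 1e-12)
    colnames(x) <- c("x1", "x2")
    x
  } else {
    clip_unit(as.vector(sig(Wd %*% o + h)), 1e-12)
  }
}

#' Integrate the rate dynamics to equilibrium
#'
#' Forward-Euler integration of the leaky dynamics
#' \code{dx/dt = -sig_inv(x) + W o + h}, a gradient flow on the network
#' cost function. Converges to \code{\link{response_fixed_point}}.
#'
#' @param o binary observation vector.
#' @param W,phi network parameters.
#' @param x0 initial state in (0, 1)^2.
#' @param step_size Euler step (default 0.1).
#' @param n_steps number of steps.
#' @return list with final \code{x} and the \code{trajectory} matrix
#'   \code{(n_steps + 1) x 2}.
#' @export
integrate_dynamics <- function(o, W, phi, x0 = c(0.5, 0.5),
                               step_size = 0.1, n_steps = 500L) {
  stopifnot(all(x0 > 0), all(x0 < 1))
  h <- threshold_from_weights(W, phi)$h
  drive <- as.vector((W$W1 - W$W0) %*% o + h)
  x <- x0
  traj <- matrix(NA_real_, n_steps + 1, 2)
  traj[1, ] <- x
  eps <- 1e-12
  for (k in seq_len(n_steps)) {
    x <- x + step_size * (-sig_inv(x) + drive)
    if (any(x <= 0) || any(x >= 1)) {
      warning("state left (0,1); clamped")
      x <- clip_unit(x, eps)
    }
    traj[k + 1, ] <- x
  }
  list(x = x, trajectory = traj)
}

#' Canonical network cost function
#'
#' The cost whose gradient flow yields both the response dynamics and the
#' plasticity rule:
#' \code{L = sum_t (x; 1-x) . (ln(x; 1-x) - ln(What-block)(o; 1-o) - (phi1; phi0))},
#' where the block matrix stacks \code{sig(W1)}, \code{1 - sig(W1)},
#' \code{sig(W0)}, \code{1 - sig(W0)}. A weight-only additive term (of
#' order below t) is omitted; it cancels in all comparisons across time at
#' fixed weights. Under the correspondence x <-> state posterior,
#' sig(W_l) <-> likelihood posterior, phi <-> log state prior, L equals the
#' variational free energy of the matched generative model, term by term in
#' the time sum.
#'
#' @param responses numeric \code{T x 2} matrix (or length-2 vector),
#'   strictly inside (0, 1).
#' @param stimuli binary \code{T x n_inputs} matrix (or vector).
#' @param W a \code{\link{synaptic_weights}} object.
#' @param phi a \code{\link{threshold_factors}} object.
#' @return scalar cost (nats).
#' @export
cost_function <- function(responses, stimuli, W, phi) {
  if (is.null(dim(responses))) responses <- matrix(responses, nrow = 1)
  if (is.null(dim(stimuli))) stimuli <- matrix(stimuli, nrow = 1)
  if (any(responses <= 0) || any(responses >= 1))
    stop("responses must lie strictly inside (0, 1)")
  W1h <- sig(W$W1); W0h <- sig(W$W0)
  # Log-likelihood blocks per trial and ensemble: T x 2 each.
  ll1 <- stimuli %*% t(log(W1h)) + (1 - stimuli) %*% t(log(1 - W1h))
  ll0 <- stimuli %*% t(log(W0h)) + (1 - stimuli) %*% t(log(1 - W0h))
  xb <- 1 - responses
  ent <- xlogx(responses) + xlogx(xb)
  acc <- responses * ll1 + xb * ll0
  pri <- responses * rep(phi$phi1, each = nrow(responses)) +
    xb * rep(phi$phi0, each = nrow(responses))
  sum(ent - acc - pri)
}

#' Time-averaged sufficient statistics of responses and stimuli
#'
#' Running averages needed by the plasticity rule and its fixed point:
#' \code{<x o'>}, \code{<(1-x) o'>}, \code{<x>}, \code{<1-x>} and the trial
#' count.
#'
#' @param responses \code{T x 2} response matrix.
#' @param stimuli \code{T x n_inputs} binary matrix.
#' @return object of class \code{sufficient_stats}.
#' @export
sufficient_stats <- function(responses, stimuli) {
  stopifnot(nrow(responses) == nrow(stimuli))
  n <- nrow(responses)
  structure(list(mean_x_o = crossprod(responses, stimuli) / n,   # 2 x n_inputs
                 mean_xbar_o = crossprod(1 - responses, stimuli) / n,
                 mean_x = colMeans(responses),
                 mean_xbar = colMeans(1 - responses),
                 n = n),
            class = "sufficient_stats")
}

#' Hebbian/homeostatic plasticity gradient
#'
#' The weight increments obtained as minus the weight gradient of the cost
#' per trial: \code{dW1 = <x o'> - <x> sig(W1)} and
#' \code{dW0 = <(1-x) o'> - <1-x> sig(W0)} (Hebbian co-activation minus an
#' activity-dependent homeostatic decay).
#'
#' @param stats a \code{\link{sufficient_stats}} object.
#' @param W a \code{\link{synaptic_weights}} object.
#' @return list with matrices \code{dW1} and \code{dW0}.
#' @export
plasticity_gradient <- function(stats, W) {
  stopifnot(stats$n >= 1)
  list(dW1 = stats$mean_x_o - stats$mean_x * sig(W$W1),
       dW0 = stats$mean_xbar_o - stats$mean_xbar * sig(W$W0))
}

#' Fixed point of the plasticity rule
#'
#' Solves the zero of the plasticity gradient:
#' \code{W1 = sig_inv(<x o'> / <x>)}, \code{W0 = sig_inv(<(1-x) o'> / <1-x>)}.
#' Ratios are clipped to \code{[clip_eps, 1 - clip_eps]} before the logit so
#' deterministic couplings stay finite. An optional Dirichlet-style prior
#' anchors the ratios at initial sigmoid-space weights with evidential mass
#' \code{lambda_w} (the inverse learning rate): the numerator and
#' denominator counts start at \code{lambda_w * sig(W_init)} and
#' \code{lambda_w} respectively.
#'
#' @param stats a \code{\link{sufficient_stats}} object.
#' @param clip_eps ratio clipping floor (default 1e-3).
#' @param prior optional list with \code{lambda_w} (scalar mass) and
#'   \code{W_init} (a \code{synaptic_weights} object).
#' @return a \code{\link{synaptic_weights}} object.
#' @export
weights_fixed_point <- function(stats, clip_eps = 1e-3, prior = NULL) {
  stopifnot(stats$n >= 1)
  n <- stats$n
  num1 <- stats$mean_x_o * n
  den1 <- stats$mean_x * n
  num0 <- stats$mean_xbar_o * n
  den0 <- stats$mean_xbar * n
  if (!is.null(prior)) {
    lw <- prior$lambda_w
    num1 <- num1 + lw * sig(prior$W_init$W1)
    num0 <- num0 + lw * sig(prior$W_init$W0)
    den1 <- den1 + lw
    den0 <- den0 + lw
  }
  if (any(den1 <= 0) || any(den0 <= 0))
    warning("silent ensemble: zero denominator in plasticity fixed point")
  r1 <- clip_unit(num1 / pmax(den1, .Machine$double.eps), clip_eps)
  r0 <- clip_unit(num0 / pmax(den0, .Machine$double.eps), clip_eps)
  synaptic_weights(sig_inv(r1), sig_inv(r0))
}

# Merge running sums of sufficient statistics (internal).
.accumulate_stats <- function(acc, responses, stimuli) {
  n <- nrow(responses)
  if (is.null(acc)) {
    acc <- list(sum_x_o = crossprod(responses, stimuli),
                sum_xbar_o = crossprod(1 - responses, stimuli),
                sum_x = colSums(responses),
                sum_xbar = colSums(1 - responses),
                n = n)
  } else {
    acc$sum_x_o <- acc$sum_x_o + crossprod(responses, stimuli)
    acc$sum_xbar_o <- acc$sum_xbar_o + crossprod(1 - responses, stimuli)
    acc$sum_x <- acc$sum_x + colSums(responses)
    acc$sum_xbar <- acc$sum_xbar + colSums(1 - responses)
    acc$n <- acc$n + n
  }
  acc
}

.stats_from_sums <- function(acc) {
  structure(list(mean_x_o = acc$sum_x_o / acc$n,
                 mean_xbar_o = acc$sum_xbar_o / acc$n,
                 mean_x = acc$sum_x / acc$n,
                 mean_xbar = acc$sum_xbar / acc$n,
                 n = acc$n),
            class = "sufficient_stats")
}

#' Simulate training of the canonical network
#'
#' Alternates fast inference and slow learning: within a session responses
#' are the fixed-point activations under the current weights; at the end of
#' each session the weights jump to the plasticity fixed point of the
#' cumulative (from trial 1) sufficient statistics, optionally anchored by
#' an inverse-learning-rate prior at the initial weights. The per-session
#' cost L is evaluated on that session's trials under the weights in force
#' during the session.
#'
#' @param stimuli a \code{stimulus_set} or binary matrix; when a matrix,
#'   supply \code{session}.
#' @param phi \code{\link{threshold_factors}} (implicit state prior).
#' @param W_init initial \code{\link{synaptic_weights}}; default
#'   \code{\link{init_weights}} with \code{seed}.
#' @param lambda_w inverse learning rate: evidential mass anchoring the
#'   weights at \code{W_init} (0 = pure empirical fixed point; large values
#'   slow plasticity, emulating NMDA-receptor blockade).
#' @param clip_eps ratio clipping for the fixed point.
#' @param session session labels per trial (if \code{stimuli} is a matrix).
#' @param seed seed for default weight initialisation.
#' @return object of class \code{network_trajectory}: \code{x} (T x 2
#'   responses), \code{W_by_session} (list of \code{synaptic_weights} in
#'   force after each session's update), \code{L} (per-session cost, nats),
#'   \code{phi}, \code{W_init}, \code{session}.
#' @export
simulate_network_training <- function(stimuli, phi, W_init = NULL,
                                      lambda_w = 0, clip_eps = 1e-3,
                                      session = NULL, seed = 1L) {
  if (inherits(stimuli, "stimulus_set")) {
    session <- stimuli$session
    obs <- stimuli$observations
  } else {
    obs <- stimuli
    if (is.null(session)) session <- rep(1L, nrow(obs))
  }
  n_inputs <- ncol(obs)
  if (is.null(W_init)) W_init <- init_weights(n_inputs, seed = seed)
  prior <- if (lambda_w > 0) list(lambda_w = lambda_w, W_init = W_init)
           else NULL
  sessions <- unique(session)
  W <- W_init
  acc <- NULL
  x_all <- matrix(NA_real_, nrow(obs), 2,
                  dimnames = list(NULL, c("x1", "x2")))
  W_by_session <- vector("list", length(sessions))
  L <- numeric(length(sessions))
  names(L) <- names(W_by_session) <- as.character(sessions)
  for (k in seq_along(sessions)) {
    idx <- which(session == sessions[k])
    O <- obs[idx, , drop = FALSE]
    X <- response_fixed_point(O, W, phi)
    x_all[idx, ] <- X
    L[k] <- cost_function(X, O, W, phi)
    acc <- .accumulate_stats(acc, X, O)
    W <- weights_fixed_point(.stats_from_sums(acc), clip_eps, prior)
    W_by_session[[k]] <- W
  }
  structure(list(x = x_all, W_by_session = W_by_session, L = L,
                 phi = phi, W_init = W_init, session = session,
                 lambda_w = lambda_w),
            class = "network_trajectory")
}

#' @export
print.network_trajectory <- function(x, ...) {
  cat(sprintf(
    "network_trajectory: %d trials, %d sessions, L[1] = %.1f, L[last] = %.1f nats\n",
    nrow(x$x), length(x$L), x$L[1], x$L[length(x$L)]))
  invisible(x)
}
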