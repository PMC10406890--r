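test_that("thresholds decompose exactly as weight and factor terms", {
  W <- synaptic_weights(matrix(0, 2, 32), matrix(0, 2, 32))
  phi <- threshold_factors(c(0, 0), c(0, 0))
  h <- threshold_from_weights(W, phi)
  expect_equal(h$h1, rep(32 * log(0.5), 2))
  expect_equal(h$h, c(0, 0))

  # Saturation: strong excitatory weights push the threshold to -Inf.
  Wbig <- synaptic_weights(matrix(30, 2, 32), matrix(0, 2, 32))
  expect_lt(max(threshold_from_weights(Wbig, phi)$h1), -900)

  W2 <- random_weights(4)
  phi2 <- random_phi(4)
  h2 <- threshold_from_weights(W2, phi2)
  expect_equal(h2$h1,
               rowSums(log(1 - sig(W2$W1))) + phi2$phi1, tolerance = 1e-12)
})

test_that("fixed-point responses satisfy the rate equation", {
  W0 <- synaptic_weights(matrix(0, 2, 32), matrix(0, 2, 32))
  phi0 <- threshold_factors(c(0, 0), c(0, 0))
  o <- rep(0L, 32)
  expect_equal(response_fixed_point(o, W0, phi0), c(0.5, 0.5))

  # Saturating drive.
  Wsat <- synaptic_weights(matrix(30 / 32, 2, 32) + 2,
                           matrix(0, 2, 32))
  phi_sat <- threshold_factors(c(60, 60), c(0, 0))
  xsat <- response_fixed_point(rep(1L, 32), Wsat, phi_sat)
  expect_lt(max(abs(xsat - 1)), 1e-9)

  # Self-consistency of random instances: the drift vanishes at the fixed
  # point.
  W <- random_weights(6)
  phi <- random_phi(6)
  set.seed(6)
  o2 <- rbinom(32, 1, 0.5)
  x <- response_fixed_point(o2, W, phi)
  h <- threshold_from_weights(W, phi)$h
  drift <- -sig_inv(x) + as.vector((W$W1 - W$W0) %*% o2 + h)
  expect_lt(max(abs(drift)), 1e-10)
})

test_that("Euler integration contracts to the fixed point along a descent", {
  W <- random_weights(8)
  phi <- random_phi(8)
  set.seed(8)
  o <- rbinom(32, 1, 0.5)
  xstar <- response_fixed_point(o, W, phi)
  # Equilibrium initialisation stays put.
  same <- integrate_dynamics(o, W, phi, x0 = xstar, n_steps = 50)
  expect_lt(max(abs(same$x - xstar)), 1e-8)
  # Arbitrary initialisation converges.
  run <- integrate_dynamics(o, W, phi, x0 = c(0.9, 0.1), n_steps = 500)
  expect_lt(max(abs(run$x - xstar)), 1e-6)
  # The cost is non-increasing along the trajectory (gradient flow).
  L_path <- apply(run$trajectory, 1, function(x)
    cost_function(x, o, W, phi))
  expect_true(all(diff(L_path) <= 1e-10))
})

test_that("cost gradient with respect to responses matches the dynamics", {
  W <- random_weights(10)
  phi <- random_phi(10)
  set.seed(10)
  o <- rbinom(32, 1, 0.5)
  x <- runif(2, 0.2, 0.8)
  h <- threshold_from_weights(W, phi)$h
  analytic <- sig_inv(x) - as.vector((W$W1 - W$W0) %*% o + h)
  eps <- 1e-6
  for (e in 1:2) {
    xp <- x; xm <- x
    xp[e] <- xp[e] + eps; xm[e] <- xm[e] - eps
    fd <- (cost_function(xp, o, W, phi) - cost_function(xm, o, W, phi)) /
      (2 * eps)
    expect_lt(abs(fd - analytic[e]), 1e-6)
  }
  # At the fixed point the gradient vanishes.
  xs <- response_fixed_point(o, W, phi)
  g0 <- sig_inv(xs) - as.vector((W$W1 - W$W0) %*% o + h)
  expect_lt(max(abs(g0)), 1e-10)
  # Degenerate responses are rejected.
  expect_error(cost_function(c(0, 0.5), o, W, phi), "strictly inside")
})

test_that("plasticity rule equals minus the per-trial weight gradient", {
  W <- random_weights(12)
  phi <- random_phi(12)
  set.seed(12)
  o <- matrix(rbinom(20 * 32, 1, 0.5), 20, 32)
  x <- matrix(runif(40, 0.1, 0.9), 20, 2)
  stats <- sufficient_stats(x, o)
  grad <- plasticity_gradient(stats, W)
  eps <- 1e-6
  for (probe in list(c(1, 3), c(2, 17))) {
    e <- probe[1]; i <- probe[2]
    Wp <- W; Wm <- W
    Wp$W1[e, i] <- Wp$W1[e, i] + eps
    Wm$W1[e, i] <- Wm$W1[e, i] - eps
    fd <- -(cost_function(x, o, Wp, phi) - cost_function(x, o, Wm, phi)) /
      (2 * eps) / nrow(x)
    expect_lt(abs(fd - grad$dW1[e, i]), 1e-6)
    Wp <- W; Wm <- W
    Wp$W0[e, i] <- Wp$W0[e, i] + eps
    Wm$W0[e, i] <- Wm$W0[e, i] - eps
    fd0 <- -(cost_function(x, o, Wp, phi) - cost_function(x, o, Wm, phi)) /
      (2 * eps) / nrow(x)
    expect_lt(abs(fd0 - grad$dW0[e, i]), 1e-6)
  }
  # All-zero responses: the excitatory increment vanishes, the inhibitory
  # one is driven by the stimulus mean.
  stats0 <- sufficient_stats(matrix(0, 20, 2), o)
  g0 <- plasticity_gradient(stats0, W)
  expect_equal(g0$dW1, matrix(0, 2, 32), ignore_attr = TRUE)
  expect_equal(g0$dW0,
               matrix(rep(colMeans(o), each = 2), 2) - sig(W$W0),
               ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("weight fixed point inverts the plasticity rule", {
  # Independence: ratio 0.5 gives weight 0.
  stats <- structure(list(mean_x_o = matrix(0.25, 2, 32),
                          mean_xbar_o = matrix(0.25, 2, 32),
                          mean_x = c(0.5, 0.5), mean_xbar = c(0.5, 0.5),
                          n = 100), class = "sufficient_stats")
  W <- weights_fixed_point(stats)
  expect_equal(W$W1, matrix(0, 2, 32), ignore_attr = TRUE)
  expect_equal(plasticity_gradient(stats, W)$dW1,
               matrix(0, 2, 32), ignore_attr = TRUE, tolerance = 1e-12)

  # Deterministic coupling hits the clip.
  stats2 <- stats
  stats2$mean_x_o[1, 1] <- 0.5
  W2 <- weights_fixed_point(stats2, clip_eps = 1e-3)
  expect_equal(W2$W1[1, 1], sig_inv(1 - 1e-3))

  # Round-trip recovery from a trained (self-consistent) network: a
  # learned weight configuration regenerates responses whose re-estimate
  # stays close, and the generate/estimate loop converges to an exact
  # fixed point within a few iterations.
  stim <- fixture_stimuli()
  phi <- prior_threshold_factors(0.5)
  net <- simulate_network_training(stim, phi, seed = 14, lambda_w = 0)
  Wg <- net$W_by_session[[100]]
  x <- response_fixed_point(stim$observations, Wg, phi)
  What <- weights_fixed_point(sufficient_stats(x, stim$observations))
  rms <- sqrt(mean((cbind(sig(What$W1), sig(What$W0)) -
                      cbind(sig(Wg$W1), sig(Wg$W0)))^2))
  expect_lt(rms, 0.05)
  gap <- Inf
  for (k in 1:3) {
    x <- response_fixed_point(stim$observations, What, phi)
    Wnext <- weights_fixed_point(sufficient_stats(x, stim$observations))
    gap <- max(abs(cbind(sig(Wnext$W1), sig(Wnext$W0)) -
                     cbind(sig(What$W1), sig(What$W0))))
    What <- Wnext
  }
  expect_lt(gap, 0.01)
})

test_that("network cost equals variational free energy under the mapping", {
  # Map responses to per-source posteriors, sigmoid weights to the
  # likelihood (additively over the two factors) and threshold factors to
  # the log prior; the time-sum parts must agree exactly.
  W <- random_weights(15)
  phi <- random_phi(15)
  set.seed(15)
  o <- matrix(rbinom(8 * 32, 1, 0.5), 8, 32)
  x <- matrix(runif(16, 0.05, 0.95), 8, 2)
  L <- cost_function(x, o, W, phi)

  lW1 <- log(sig(W$W1)); lW1b <- log(1 - sig(W$W1))
  lW0 <- log(sig(W$W0)); lW0b <- log(1 - sig(W$W0))
  lnA <- array(NA_real_, dim = c(32, 2, 4))
  kk <- c(1, 1, 2, 2); ll <- c(1, 2, 1, 2)
  pick <- function(lon, loff, lev) if (lev == 1) lon else loff
  for (st in 1:4) {
    lnA[, 1, st] <- pick(lW1[1, ], lW0[1, ], kk[st]) +
      pick(lW1[2, ], lW0[2, ], ll[st])
    lnA[, 2, st] <- pick(lW1b[1, ], lW0b[1, ], kk[st]) +
      pick(lW1b[2, ], lW0b[2, ], ll[st])
  }
  ln_d <- rbind(c(phi$phi1[1], phi$phi0[1]), c(phi$phi1[2], phi$phi0[2]))
  posts <- t(apply(x, 1, function(r) joint_from_marginals(r[1], r[2])))
  F_val <- free_energy(posts, o, lnA, ln_d)
  expect_equal(L, F_val, tolerance = 1e-9)
})

test_that("training develops source specificity with a descending cost", {
  stim <- fixture_stimuli()
  net <- fixture_network()
  sp1 <- specificity_statistic(net$x, stim$sources, stim$session, 1)
  sp2 <- specificity_statistic(net$x, stim$sources, stim$session, 2)
  avg_diff <- (sp1$difference + sp2$difference) / 2
  # The ON/OFF response difference grows strongly from session 1.
  expect_gt(avg_diff[100], avg_diff[1] + 0.2)
  expect_gt((sp1$specificity[100] + sp2$specificity[100]) / 2, 0.2)
  # Per-session cost is non-increasing under the repeated stimulus
  # sequence (gradient flow with cumulative statistics).
  L <- net$L
  expect_true(all(diff(L) <= 1e-6 * abs(L[-length(L)])))
  # The two ensembles specialise to opposite input groups: ensemble 1's
  # left-minus-right excitatory contrast exceeds ensemble 2's.
  W <- net$W_by_session[[100]]
  contrast <- function(e) mean(sig(W$W1[e, 1:16])) - mean(sig(W$W1[e, 17:32]))
  expect_gt(contrast(1) - contrast(2), 0.05)
  expect_gt(cor(net$x[, 1], stim$sources[, 1]), 0.5)
  expect_gt(cor(net$x[, 2], stim$sources[, 2]), 0.5)
})

test_that("network and ideal observer trajectories agree closely", {
  des <- experiment_design(n_sessions = 30, trials_per_session = 256,
                           seed = 5, repeat_identical_sequence = FALSE)
  stim <- generate_session_stimuli(des)
  net <- simulate_network_training(stim, prior_threshold_factors(0.5),
                                   seed = 5)
  obs <- run_ideal_observer(stim, state_prior(), seed = 5)
  # The network is the per-factor (marginal) formulation, the observer the
  # joint-tensor one with explaining-away; their state estimates agree
  # strongly without being identical.
  agreement <- diag(cor(net$x, obs$posterior_on))
  expect_true(all(agreement > 0.8))
})

test_that("easier unmixed stimuli speed up the cost reduction", {
  halve_session <- function(mix) {
    des <- experiment_design(n_sessions = 60, mix_fraction = mix, seed = 19)
    stim <- generate_session_stimuli(des)
    net <- simulate_network_training(stim, prior_threshold_factors(0.5),
                                     seed = 19, lambda_w = 2560)
    dL <- net$L - net$L[1]
    list(half = which(dL <= dL[length(dL)] / 2)[1], total = dL[length(dL)])
  }
  easy <- halve_session(0)
  standard <- halve_session(0.25)
  expect_lte(easy$half, standard$half)
  expect_lt(easy$total, standard$total)
})
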