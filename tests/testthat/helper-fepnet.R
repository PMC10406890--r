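# Shared fixtures, built in code. Small designs keep unit tests fast; the
# acceptance suite uses full-size runs.

small_design <- function(n_sessions = 20L, trials = 64L, seed = 1L, ...) {
  experiment_design(n_sessions = n_sessions, trials_per_session = trials,
                    seed = seed, ...)
}

# A modest control-condition stimulus set shared across tests.
fixture_stimuli <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- generate_session_stimuli(experiment_design(seed = 42L))
    cache
  }
})

# A full control network simulation on the fixture stimuli.
fixture_network <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- simulate_network_training(fixture_stimuli(),
                                          prior_threshold_factors(0.5),
                                          seed = 42L, lambda_w = 2560)
    cache
  }
})

# A control synthetic recording plus preprocessing products.
fixture_recording <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      des <- experiment_design(seed = 77L)
      rec <- generate_recording(des, synthetic_config(seed = 77L))
      cls <- classify_electrodes(rec)
      ens <- ensemble_responses(rec, cls)
      cache <<- list(rec = rec, cls = cls, ens = ens)
    }
    cache
  }
})

random_weights <- function(seed = 1L, scale = 0.5, n_inputs = 32L) {
  set.seed(seed)
  synaptic_weights(matrix(stats::rnorm(2 * n_inputs, 0, scale), 2, n_inputs),
                   matrix(stats::rnorm(2 * n_inputs, 0, scale), 2, n_inputs))
}

random_phi <- function(seed = 1L) {
  set.seed(seed)
  threshold_factors(stats::rnorm(2, -0.7, 0.3), stats::rnorm(2, -0.7, 0.3))
}
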