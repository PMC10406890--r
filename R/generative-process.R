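#' State prior over the two binary sources
#'
#' The generative process samples each hidden source independently from a
#' categorical (Bernoulli) distribution with ON probability \code{d1}. The
#' complementary OFF probability is \code{d0 = 1 - d1}.
#'
#' @param d1_source1,d1_source2 ON prior probability of sources 1 and 2.
#' @return object of class \code{state_prior} with fields \code{d1} and
#'   \code{d0} (length-2 vectors, one entry per source).
#' @export
state_prior <- function(d1_source1 = 0.5, d1_source2 = 0.5) {
  d1 <- c(d1_source1, d1_source2)
  if (any(!is.finite(d1)) || any(d1 < 0) || any(d1 > 1))
    stop("state prior probabilities must lie in [0, 1]")
  structure(list(d1 = d1, d0 = 1 - d1), class = "state_prior")
}

#' @export
print.state_prior <- function(x, ...) {
  cat(sprintf("state_prior: P(s1=1) = %.3f, P(s2=1) = %.3f\n",
              x$d1[1], x$d1[2]))
  invisible(x)
}

#' Build the stimulus mixing (likelihood) tensor
#'
#' Each of the \code{n_inputs} stimulation channels carries a stochastic
#' mixture of the two sources. For mixing fraction \code{m}, the ON
#' probability of a left-group input given joint state
#' (1,1), (1,0), (0,1), (0,0) is \code{(1, 1-m, m, 0)}; right-group inputs
#' use \code{(1, m, 1-m, 0)}. OFF probabilities are complementary. At the
#' standard 25\% mix, left inputs follow source 1 with probability 0.75.
#'
#' @param mix_fraction mixing fraction in [0, 0.5]; 0 is the unmixed
#'   (separable) limit, 0.5 the uniformly mixed (inseparable) limit.
#' @param n_inputs even number of stimulation channels (default 32).
#' @return object of class \code{mixing_matrix}: numeric array with
#'   dimensions \code{[n_inputs, 2, 4]} (observation value ON/OFF by joint
#'   source state), plus a \code{group} attribute labelling the left/right
#'   halves.
#' @export
build_mixing_matrix <- function(mix_fraction, n_inputs = 32L) {
  if (!is.finite(mix_fraction) || mix_fraction < 0 || mix_fraction > 0.5)
    stop("mix_fraction must lie in [0, 0.5]")
  if (n_inputs < 2 || n_inputs %% 2 != 0)
    stop("n_inputs must be a positive even number")
  m <- mix_fraction
  left_on <- c(1, 1 - m, m, 0)
  right_on <- c(1, m, 1 - m, 0)
  A <- array(NA_real_, dim = c(n_inputs, 2L, 4L),
             dimnames = list(NULL, c("on", "off"), .joint_labels))
  half <- n_inputs / 2
  for (st in 1:4) {
    A[1:half, "on", st] <- left_on[st]
    A[(half + 1):n_inputs, "on", st] <- right_on[st]
  }
  A[, "off", ] <- 1 - A[, "on", ]
  structure(A,
            group = rep(c("left", "right"), each = half),
            mix_fraction = m,
            class = "mixing_matrix")
}

#' Experiment design
#'
#' Captures the training protocol: a fixed number of sessions, each a
#' sequence of stimulation trials. By default every session replays the
#' session-1 stimulus sequence (100 sessions of an identical 256-step
#' sequence), matching the standard training protocol.
#'
#' @param n_sessions number of training sessions.
#' @param trials_per_session stimulation trials per session.
#' @param mix_fraction source mixing fraction (see
#'   \code{\link{build_mixing_matrix}}).
#' @param prior \code{\link{state_prior}} of the generative process.
#' @param n_inputs number of stimulation channels.
#' @param seed master seed; sub-streams for sources, observations and
#'   synthetic noise are derived from it.
#' @param repeat_identical_sequence if \code{TRUE} every session replays the
#'   session-1 source/stimulus sequence.
#' @return object of class \code{experiment_design}.
#' @export
experiment_design <- function(n_sessions = 100L, trials_per_session = 256L,
                              mix_fraction = 0.25, prior = state_prior(),
                              n_inputs = 32L, seed = 1L,
                              repeat_identical_sequence = TRUE) {
  stopifnot(n_sessions >= 1, trials_per_session >= 1)
  structure(list(n_sessions = as.integer(n_sessions),
                 trials_per_session = as.integer(trials_per_session),
                 mix_fraction = mix_fraction,
                 prior = prior,
                 n_inputs = as.integer(n_inputs),
                 seed = as.integer(seed),
                 repeat_identical_sequence = isTRUE(repeat_identical_sequence)),
            class = "experiment_design")
}

#' Sample hidden source sequences
#'
#' Sources are i.i.d. across trials and mutually independent, with
#' \code{P(s_j = 1) = d1[j]}.
#'
#' @param prior a \code{\link{state_prior}}.
#' @param n_trials number of trials to draw.
#' @param seed integer seed for this stream.
#' @return integer matrix \code{n_trials x 2} with entries in \{0, 1\}.
#' @export
sample_sources <- function(prior, n_trials, seed = 1L) {
  stopifnot(inherits(prior, "state_prior"), n_trials >= 1)
  set.seed(seed)
  s1 <- stats::rbinom(n_trials, 1L, prior$d1[1])
  s2 <- stats::rbinom(n_trials, 1L, prior$d1[2])
  cbind(s1 = s1, s2 = s2)
}

#' Sample stimulus observations given sources
#'
#' Each input fires independently given the joint source state, with ON
#' probability taken from the mixing tensor.
#'
#' @param sources integer matrix \code{T x 2} of source states.
#' @param A a \code{\link{build_mixing_matrix}} tensor.
#' @param seed integer seed for this stream.
#' @return integer matrix \code{T x n_inputs} with entries in \{0, 1\}.
#' @export
sample_observations <- function(sources, A, seed = 1L) {
  if (ncol(sources) != 2L) stop("sources must have two columns")
  n_inputs <- dim(A)[1]
  st <- joint_state_index(sources[, 1], sources[, 2])
  p_on <- t(A[, "on", st, drop = TRUE])      # T x n_inputs
  set.seed(seed)
  o <- matrix(stats::rbinom(length(p_on), 1L, as.vector(p_on)),
              nrow = nrow(sources), ncol = n_inputs)
  colnames(o) <- sprintf("o_%02d", seq_len(n_inputs))
  o
}

#' Generate the full stimulus sequence of an experiment
#'
#' Draws sources and observations for every session of a design. When the
#' design repeats an identical sequence, the session-1 draw is replayed
#' bit-exactly in every later session.
#'
#' @param design an \code{\link{experiment_design}}.
#' @return object of class \code{stimulus_set}: list with integer matrices
#'   \code{sources} (T x 2) and \code{observations} (T x n_inputs), vectors
#'   \code{session} and \code{trial} (1-based labels), the mixing tensor
#'   \code{A} and the design.
#' @export
generate_session_stimuli <- function(design) {
  stopifnot(inherits(design, "experiment_design"))
  A <- build_mixing_matrix(design$mix_fraction, design$n_inputs)
  tps <- design$trials_per_session
  ns <- design$n_sessions
  if (design$repeat_identical_sequence) {
    s1 <- sample_sources(design$prior, tps, spawn_seed(design$seed, 1L))
    o1 <- sample_observations(s1, A, spawn_seed(design$seed, 2L))
    sources <- s1[rep(seq_len(tps), ns), , drop = FALSE]
    obs <- o1[rep(seq_len(tps), ns), , drop = FALSE]
  } else {
    sources <- sample_sources(design$prior, tps * ns,
                              spawn_seed(design$seed, 1L))
    obs <- sample_observations(sources, A, spawn_seed(design$seed, 2L))
  }
  structure(list(sources = sources,
                 observations = obs,
                 session = rep(seq_len(ns), each = tps),
                 trial = rep(seq_len(tps), ns),
                 A = A,
                 design = design),
            class = "stimulus_set")
}

#' @export
print.stimulus_set <- function(x, ...) {
  cat(sprintf(
    "stimulus_set: %d sessions x %d trials, %d inputs, mix %.0f%%%s\n",
    x$design$n_sessions, x$design$trials_per_session,
    x$design$n_inputs, 100 * x$design$mix_fraction,
    if (x$design$repeat_identical_sequence) ", identical sequence/session"
    else ""))
  invisible(x)
}

# Serialization ---------------------------------------------------------------

#' Write a stimulus set to CSV
#'
#' Columns: \code{session, trial, s1, s2, o_01..o_NN} (0/1 integers). A
#' round-trip through \code{\link{read_stimuli}} reproduces the matrices
#' exactly.
#'
#' @param stim a \code{stimulus_set} (or a list with \code{sources},
#'   \code{observations}, \code{session}, \code{trial}).
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_stimuli <- function(stim, path) {
  df <- data.frame(session = stim$session, trial = stim$trial,
                   s1 = stim$sources[, 1], s2 = stim$sources[, 2])
  df <- cbind(df, as.data.frame(stim$observations))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a stimulus CSV written by \code{\link{write_stimuli}}
#'
#' @param path file path.
#' @return list with \code{sources}, \code{observations}, \code{session},
#'   \code{trial}; zero-row files yield 0-trial matrices.
#' @export
read_stimuli <- function(path) {
  df <- utils::read.csv(path)
  ocols <- grep("^o_", names(df))
  list(sources = as.matrix(df[, c("s1", "s2"), drop = FALSE]),
       observations = as.matrix(df[, ocols, drop = FALSE]),
       session = df$session, trial = df$trial)
}

#' Write / read an experiment design as JSON or YAML
#'
#' The format follows the file extension (\code{.json} or \code{.yaml} /
#' \code{.yml}).
#'
#' @param design an \code{\link{experiment_design}}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_design <- function(design, path) {
  rec <- list(n_sessions = design$n_sessions,
              trials_per_session = design$trials_per_session,
              mix_fraction = design$mix_fraction,
              d1_source1 = design$prior$d1[1],
              d1_source2 = design$prior$d1[2],
              n_inputs = design$n_inputs,
              seed = design$seed,
              repeat_identical_sequence = design$repeat_identical_sequence)
  if (grepl("\\.ya?ml$", path)) {
    yaml::write_yaml(rec, path)
  } else {
    jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' @rdname write_design
#' @export
read_design <- function(path) {
  rec <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
         else jsonlite::read_json(path, simplifyVector = TRUE)
  experiment_design(n_sessions = rec$n_sessions,
                    trials_per_session = rec$trials_per_session,
                    mix_fraction = rec$mix_fraction,
                    prior = state_prior(rec$d1_source1, rec$d1_source2),
                    n_inputs = rec$n_inputs,
                    seed = rec$seed,
                    repeat_identical_sequence = rec$repeat_identical_sequence)
}
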