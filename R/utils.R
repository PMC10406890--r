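#' Logistic sigmoid
#'
#' Elementwise logistic function \code{1 / (1 + exp(-x))}, the activation
#' function of the canonical rate-coding network.
#'
#' @param x numeric vector, matrix or array.
#' @return object of the same shape with values in (0, 1).
#' @export
sig <- function(x) 1 / (1 + exp(-x))

#' Inverse sigmoid (logit)
#'
#' @param p numeric in (0, 1); values at 0 or 1 produce infinite output.
#' @return \code{log(p / (1 - p))}, same shape as \code{p}.
#' @export
sig_inv <- function(p) log(p) - log1p(-p)

# Clip probabilities away from {0, 1} so logs and logits stay finite.
clip_unit <- function(p, eps) pmin(pmax(p, eps), 1 - eps)

# Probability floor used inside logarithms (posteriors can be numerically 0).
.log_floor <- 1e-8

safe_log <- function(p) log(pmax(p, .log_floor))

# x * log(x) with the convention 0 * log(0) = 0.
xlogx <- function(p) ifelse(p > 0, p * log(p), 0)

# Deterministic sub-stream seeds derived from a master seed, kept inside the
# 32-bit integer range. Distinct offsets give independently reusable streams.
spawn_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 1000003 + 7919 * as.numeric(offset)) %%
               2147483629L)
}

# Joint-state bookkeeping -----------------------------------------------------
# The two binary sources define four joint states, always ordered
# (1,1), (1,0), (0,1), (0,0).

.joint_states <- rbind(c(1L, 1L), c(1L, 0L), c(0L, 1L), c(0L, 0L))
.joint_labels <- c("s11", "s10", "s01", "s00")

# Map per-trial (s1, s2) to the joint-state index 1..4.
joint_state_index <- function(s1, s2) {
  (1L - as.integer(s1)) * 2L + (1L - as.integer(s2)) + 1L
}

# Joint probability vector over the four states from per-source ON
# probabilities (independent sources).
joint_from_marginals <- function(p1_on, p2_on) {
  c(p1_on * p2_on, p1_on * (1 - p2_on),
    (1 - p1_on) * p2_on, (1 - p1_on) * (1 - p2_on))
}
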