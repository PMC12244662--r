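## Variable-order fractional velocity memory.
##
## The inertia term of the PSO velocity update is replaced by a truncated
## Grünwald-Letnikov (GL) series over past velocities. The GL expansion of
## a fractional derivative of order alpha assigns the current velocity the
## weight alpha and each older velocity a Pochhammer/gamma-ratio weight:
##   c_1 = alpha,  c_{k+1} = c_k * (k - alpha) / (k + 1).
## At alpha = 1 only c_1 = 1 survives and the classical unit-inertia update
## is recovered exactly.

#' Grünwald-Letnikov memory coefficients
#'
#' Weights on the current and past velocities in the fractional inertia
#' term, for order `alpha` and truncation depth `depth`.
#'
#' @param alpha Fractional order, `alpha > 0` (orders in `(0, 1]` give the
#'   usual decaying positive memory).
#' @param depth Number of coefficients (memory depth), `>= 1`.
#' @return Numeric vector `c_1..c_depth`; `c_1 == alpha`.
#' @examples
#' glCoefficients(0.5, 4)  # 0.5 0.125 0.0625 0.0390625
#' @export
glCoefficients <- function(alpha, depth) {
  if (!is.numeric(alpha) || length(alpha) != 1L || !is.finite(alpha) ||
      alpha <= 0)
    stop("alpha must be a positive finite number", call. = FALSE)
  depth <- as.integer(depth)
  if (is.na(depth) || depth < 1L)
    stop("depth must be a positive integer", call. = FALSE)
  cs <- numeric(depth)
  cs[1L] <- alpha
  if (depth > 1L)
    for (k in seq_len(depth - 1L))
      cs[k + 1L] <- cs[k] * (k - alpha) / (k + 1)
  cs
}

#' Linear variable-order schedule
#'
#' The fractional order decreases linearly from `alphaHi` at iteration 0 to
#' `alphaLo` at iteration `T` (high order early for fast convergence, lower
#' order late for longer memory / exploration). With `alphaLo == alphaHi`
#' the schedule is constant (fixed-order special case).
#'
#' @param t Iteration, `0 <= t <= T`.
#' @param T Maximum iteration count, `>= 0`.
#' @param alphaLo,alphaHi Order range, `0 < alphaLo <= alphaHi`.
#' @return The order at iteration `t`.
#' @export
alphaSchedule <- function(t, T, alphaLo = 0.6, alphaHi = 1.0) {
  if (alphaLo <= 0 || alphaLo > alphaHi)
    stop("need 0 < alphaLo <= alphaHi", call. = FALSE)
  if (t < 0 || t > T) stop("t outside [0, T]", call. = FALSE)
  if (T == 0) return(alphaHi)
  alphaHi - (alphaHi - alphaLo) * (t / T)
}

#' Fractional velocity memory term
#'
#' The truncated GL series `sum_k c_k(alpha) * v_{t-k+1}` over the velocity
#' history, component-wise. Histories shorter than `depth` are implicitly
#' zero-padded. This term replaces `w * v_t` in the classical velocity
#' update; at `alpha = 1` (any depth) it returns `v_t` exactly.
#'
#' @param history List of numeric vectors (or a matrix with one row per
#'   lag), most recent first: `v_t`, `v_{t-1}`, ...
#' @param alpha Fractional order.
#' @param depth Memory depth (default 4).
#' @return Numeric vector, the memory contribution to the new velocity.
#' @export
fractionalVelocityTerm <- function(history, alpha, depth = 4L) {
  if (is.matrix(history))
    history <- lapply(seq_len(nrow(history)), function(i) history[i, ])
  if (!is.list(history) || length(history) == 0L)
    stop("history must hold at least one velocity vector", call. = FALSE)
  cs <- glCoefficients(alpha, depth)
  out <- numeric(length(history[[1L]]))
  for (k in seq_len(min(depth, length(history))))
    out <- out + cs[k] * history[[k]]
  out
}
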