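# Variational free energy for a categorical posterior: the objective, its
# gradient (the prediction error), the exact-posterior oracle, and a
# convexity diagnostic. The per-observation context bundles the two log
# terms of ln P(o, s) = ln P(o | s) + ln P(s).

#' Free-energy context for one observation
#'
#' Bundles the log-likelihood evidence (the observation's row of ln A) and
#' the log-prior over states (ln D for the first step, ln(B %*% s_prev)
#' afterwards). Non-finite or very small entries are clamped at
#' `log(PROB_FLOOR)` so the free energy is finite everywhere on the
#' (floored) simplex.
#'
#' @param log_lik numeric vector over states: ln P(o | s) for the observed o.
#' @param log_prior numeric vector over states: ln P(s).
#' @return an object of class `fe_context`.
#' @export
fe_context <- function(log_lik, log_prior) {
  if (length(log_lik) != length(log_prior))
    stop("fe_context: log_lik and log_prior must have equal length")
  clamp <- function(x) {
    if (any(is.nan(x) | x == Inf)) stop("fe_context: NaN or +Inf input")
    pmax(x, log(PROB_FLOOR))
  }
  structure(list(log_lik = clamp(log_lik), log_prior = clamp(log_prior)),
            class = "fe_context")
}

#' Variational free energy of a categorical belief
#'
#' `F(s) = sum_i s_i (ln s_i - ln P(s_i) - ln P(o | s_i))`, the
#' KL divergence of the belief from the exact posterior minus the log
#' evidence; equivalently complexity minus accuracy. The convention
#' `0 * ln 0 = 0` is applied.
#'
#' @param s belief vector.
#' @param ctx an `fe_context`.
#' @return scalar free energy in nats.
#' @export
free_energy <- function(s, ctx) {
  s <- as_belief(s)
  if (length(s) != length(ctx$log_lik))
    stop("free_energy: dimension mismatch")
  lg <- ifelse(s > 0, log(pmax(s, PROB_FLOOR)), 0)
  sum(s * (lg - ctx$log_prior - ctx$log_lik))
}

#' Free-energy gradient (prediction error)
#'
#' `ln s - ln P(s) - ln P(o | s)`: the discrepancy between log-beliefs and
#' log-prior-plus-evidence. The additive constant (+1 from the entropy
#' term) is omitted as it is annihilated by the softmax. The gradient is
#' constant across components (a softmax-invariant zero) exactly at the
#' posterior.
#'
#' @param s belief vector; boundary beliefs are floored with a warning.
#' @param ctx an `fe_context`.
#' @return numeric gradient vector.
#' @export
free_energy_gradient <- function(s, ctx) {
  if (any(s < PROB_FLOOR)) {
    warning("boundary belief floored before gradient evaluation")
    s <- floor_beliefs(s)
  }
  log(s) - ctx$log_prior - ctx$log_lik
}

#' Exact posterior for a free-energy context
#'
#' The Bayes posterior `softmax(ln P(s) + ln P(o | s))`; the unique
#' minimiser of the free energy, used throughout as an oracle.
#'
#' @param ctx an `fe_context`.
#' @return belief vector.
#' @export
exact_posterior <- function(ctx) {
  softmax(ctx$log_prior + ctx$log_lik)
}

#' Convexity diagnostic: tangent-space Hessian of the free energy
#'
#' The Hessian of F on the open simplex is `diag(1/s)`. This reports its
#' positive-definiteness restricted to the simplex tangent space (the
#' hyperplane orthogonal to the all-ones direction) together with the
#' minimal tangent eigenvalue.
#'
#' @param ctx an `fe_context` (the Hessian does not depend on it; kept for
#'   interface symmetry).
#' @param s interior belief vector.
#' @return list with `psd` (logical) and `min_eigenvalue` (smallest
#'   eigenvalue of the tangent-restricted Hessian).
#' @export
free_energy_hessian_psd <- function(ctx, s) {
  s <- as_belief(s)
  if (any(s <= 0)) stop("free_energy_hessian_psd: s must be interior")
  n <- length(s)
  P <- diag(n) - matrix(1 / n, n, n)   # projector onto the tangent space
  M <- P %*% diag(1 / s, nrow = n) %*% P
  ev <- sort(eigen(M, symmetric = TRUE, only.values = TRUE)$values)
  # the all-ones direction contributes one (numerically) zero eigenvalue
  min_tangent <- ev[2L]
  list(psd = min_tangent > 0, min_eigenvalue = min_tangent)
}
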