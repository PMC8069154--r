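# Perceptual inference: the two belief-update schemes, trajectory
# recording, and simulated electrophysiology. Beliefs s are firing rates;
# v = ln s (up to an additive constant) is the voltage code, and the rate
# of change of v is read out as a simulated local field potential.

#' One active-inference belief update
#'
#' `s <- softmax(ln s - eps * grad F)`: a forward-Euler discretisation of
#' the softmax-mediated free-energy descent. Equals
#' `s * exp(-eps * grad)` renormalised, and always returns a point on the
#' simplex.
#'
#' @param s belief vector (floored internally).
#' @param ctx an `fe_context`.
#' @param epsilon positive step size (0.25 throughout the experiments).
#' @return updated belief vector.
#' @export
ai_update <- function(s, ctx, epsilon = 0.25) {
  if (epsilon < 0) stop("ai_update: epsilon must be non-negative")
  s <- floor_beliefs(s)
  g <- log(s) - ctx$log_prior - ctx$log_lik
  softmax(log(s) - epsilon * g)
}

#' One natural-gradient belief update
#'
#' `s <- (s - eps * g^{-1}(s) grad F)~` where `g^{-1}(s) = diag(s)` and `~`
#' is the simplest projection back onto the simplex: negative
#' pre-normalisation components are clipped to zero and the iterate is
#' normalised by its component sum. At the exact posterior the gradient is
#' constant, the update is a uniform rescaling, and the belief is a fixed
#' point.
#'
#' The clipped Euler step is aggressive on steep (near-deterministic)
#' contexts, and on rare belief/context configurations the bare update can
#' overshoot so badly that the free energy rises (the dominant component's
#' linear factor changes sign). The update therefore backtracks: whenever
#' an iterate would increase the free energy the step is halved and
#' retried, returning the current belief (with a warning) only if halving
#' fails entirely. The safeguard leaves well-behaved steps - including the
#' convergent jumps on deterministic task contexts - untouched.
#'
#' @inheritParams ai_update
#' @return updated belief vector.
#' @export
ng_update <- function(s, ctx, epsilon = 0.25) {
  if (epsilon < 0) stop("ng_update: epsilon must be non-negative")
  s <- floor_beliefs(s)
  g <- log(s) - ctx$log_prior - ctx$log_lik
  f0 <- free_energy(s, ctx)
  step <- epsilon
  for (k in seq_len(30L)) {
    w <- pmax(s - step * (s * g), 0)
    if (sum(w) > 0) {
      cand <- floor_beliefs(w / sum(w))
      if (free_energy(cand, ctx) <= f0 + 1e-12) return(cand)
    }
    step <- step / 2
  }
  warning("ng_update: backtracking failed to reduce the free energy; belief unchanged")
  s
}

#' Run perceptual inference to (approximate) convergence
#'
#' Iterates the chosen scheme from `s0` until the tangent-gradient norm
#' falls below `tol` or `max_iter` updates have been applied, recording the
#' belief and voltage trajectory, per-iterate free energies and gradient
#' norms, and the accumulated information length of the belief path.
#'
#' The stationarity measure is the norm of the free-energy gradient
#' projected onto the simplex tangent space through the softmax chart,
#' `||(diag(s) - s s^T) grad F||` - the instantaneous rate of belief
#' change. (The raw Euclidean gradient never vanishes on floored boundary
#' components under deterministic likelihoods, whereas this measure does.)
#' Because that norm is blind to components that have been floored but still
#' carry mass in the exact posterior, convergence additionally requires that
#' no component's gradient lies more than 0.01 below the belief-weighted
#' mean gradient - i.e. that no under-massed component still wants to grow.
#'
#' @param s0 initial belief (e.g. the predictive prior, or the uniform
#'   mid-simplex point).
#' @param ctx an `fe_context`.
#' @param scheme `"active_inference"` or `"natural_gradient"`.
#' @param epsilon step size.
#' @param max_iter maximum number of updates.
#' @param tol convergence tolerance on the tangent-gradient norm.
#' @param distance information-distance form for the recorded path.
#' @return an object of class `inference_trace`: `beliefs` and `voltages`
#'   (matrices, one row per iterate including the initial point),
#'   `gradient_norms`, `free_energies`, `info_path`, `converged`,
#'   `iterations`, `scheme`, `epsilon`.
#' @export
run_inference <- function(s0, ctx,
                          scheme = c("active_inference", "natural_gradient"),
                          epsilon = 0.25, max_iter = 64L, tol = 1e-4,
                          distance = c("chord", "arc")) {
  scheme <- match.arg(scheme)
  distance <- match.arg(distance)
  upd <- if (scheme == "active_inference") ai_update else ng_update
  s <- floor_beliefs(as_belief(s0))
  n <- length(s)
  beliefs <- matrix(NA_real_, max_iter + 1L, n)
  fes <- gnorms <- numeric(max_iter + 1L)
  converged <- FALSE
  k <- 0L
  repeat {
    beliefs[k + 1L, ] <- s
    fes[k + 1L] <- free_energy(s, ctx)
    g <- log(s) - ctx$log_prior - ctx$log_lik
    err <- g - sum(s * g)               # deviation from weighted mean
    gnorms[k + 1L] <- sqrt(sum((s * err)^2))   # (diag(s) - s s^T) grad
    if (gnorms[k + 1L] < tol && min(err) > -1e-2) { converged <- TRUE; break }
    if (k >= max_iter) break
    s <- upd(s, ctx, epsilon)
    if (any(!is.finite(s)))
      stop("run_inference: non-finite iterate at iteration ", k + 1L)
    k <- k + 1L
  }
  keep <- seq_len(k + 1L)
  beliefs <- beliefs[keep, , drop = FALSE]
  structure(list(beliefs = beliefs,
                 voltages = log(beliefs),
                 gradient_norms = gnorms[keep],
                 free_energies = fes[keep],
                 info_path = path_information_length(beliefs, distance),
                 converged = converged,
                 iterations = k + 1L,
                 scheme = scheme, epsilon = epsilon),
            class = "inference_trace")
}

#' @export
print.inference_trace <- function(x, ...) {
  cat("<inference_trace> ", x$scheme, ", ", x$iterations, " iterates, ",
      if (x$converged) "converged" else "not converged",
      ", information length ", format(x$info_path$total_length, digits = 6),
      "\n", sep = "")
  invisible(x)
}

#' Simulated local field potentials from an inference trace
#'
#' Interprets the rate of change of the voltage code as depolarisations:
#' row t is `v(t+1) - v(t)`. As the rate of change is the (negative)
#' free-energy gradient, the rows decay to zero as the free-energy minimum
#' is reached.
#'
#' @param trace an `inference_trace`.
#' @return an `(iterations - 1) x n_states` matrix; empty (0-row) for a
#'   single-iterate trace.
#' @export
simulated_lfp <- function(trace) {
  v <- trace$voltages
  if (nrow(v) < 2L) return(v[0L, , drop = FALSE])
  diff(v)
}

#' Export an inference trace as tidy CSV
#'
#' One row per (iteration, state): iteration index, state index, belief,
#' voltage, simulated LFP (NA on the first iterate) and the cumulative
#' information length up to that iteration.
#'
#' @param trace an `inference_trace`.
#' @param path output CSV path.
#' @export
trace_to_csv <- function(trace, path) {
  n <- ncol(trace$beliefs)
  it <- nrow(trace$beliefs)
  lfp <- rbind(matrix(NA_real_, 1L, n), simulated_lfp(trace))
  cum <- c(0, cumsum(trace$info_path$step_distances))
  df <- data.frame(
    iteration = rep(seq_len(it), each = n),
    state = rep(seq_len(n), times = it),
    belief = as.vector(t(trace$beliefs)),
    voltage = as.vector(t(trace$voltages)),
    lfp = as.vector(t(lfp)),
    cumulative_information_length = rep(cum, each = n))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
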