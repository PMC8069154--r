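# Information geometry of the categorical simplex: the Fisher-Rao metric,
# information distances, path lengths and geodesics. All quantities are on
# the nats scale. The square-root ("sphere") embedding s -> sqrt(s) maps the
# simplex isometrically (up to a factor 2) onto the positive orthant of the
# unit sphere, which is what makes the closed forms below exact.

#' Numerical floor applied to probabilities before logarithms and metric
#' operations. Metric quantities diverge on the simplex boundary, so beliefs
#' are floored at this value and renormalised.
#' @export
PROB_FLOOR <- 1e-16

#' Validate a belief vector
#'
#' A belief vector is a point on the (n-1)-simplex: a numeric vector of
#' n >= 2 non-negative components summing to one. Returns the vector
#' unchanged (so it can be used inline) or throws an informative error.
#'
#' @param p numeric vector of probabilities.
#' @param tol tolerance on the sum-to-one constraint.
#' @return `p`, invisibly validated.
#' @export
as_belief <- function(p, tol = 1e-8) {
  if (!is.numeric(p) || length(p) < 2L)
    stop("a belief must be a numeric vector of length >= 2")
  if (any(!is.finite(p)))
    stop("belief components must be finite")
  if (any(p < -tol))
    stop("belief components must be non-negative")
  if (abs(sum(p) - 1) > tol)
    stop("belief components must sum to 1 (got ", format(sum(p)), ")")
  p
}

#' Floor a belief away from the simplex boundary
#'
#' Components below `floor` are raised to it and the vector is renormalised.
#' All geometric and logarithmic operations in the package assume beliefs
#' have been floored.
#'
#' @param p numeric probability vector.
#' @param floor boundary floor (default [PROB_FLOOR]).
#' @return floored, renormalised probability vector.
#' @export
floor_beliefs <- function(p, floor = PROB_FLOOR) {
  p <- pmax(p, floor)
  p / sum(p)
}

#' Softmax map from potentials to beliefs
#'
#' Maps an unconstrained real vector v (the "voltage" or log-probability
#' code) to a belief vector exp(v)/sum(exp(v)). Computed shift-invariantly
#' (the maximum is subtracted first), so `softmax(v + c)` equals
#' `softmax(v)` for any constant c.
#'
#' @param v finite numeric vector.
#' @return a belief vector of the same length.
#' @export
softmax <- function(v) {
  if (!is.numeric(v) || any(!is.finite(v)))
    stop("softmax: input must be a finite numeric vector")
  w <- exp(v - max(v))
  w / sum(w)
}

#' Inverse Fisher information metric on the simplex
#'
#' On the categorical simplex the inverse of the Fisher information metric
#' tensor is simply `diag(s)`. Its action on a gradient is therefore the
#' elementwise product `s * u`.
#'
#' @param s interior belief vector.
#' @return the n x n diagonal matrix `diag(s)`.
#' @export
inverse_fisher_metric <- function(s) {
  s <- as_belief(s)
  if (any(s <= 0))
    warning("belief lies on the simplex boundary; floor beliefs before metric operations")
  diag(s, nrow = length(s))
}

#' Fisher-Rao information distance between two categorical beliefs
#'
#' The default `"chord"` form is 2 * ||sqrt(a) - sqrt(b)||, the Euclidean
#' distance between the sphere embeddings (scaled by the factor 2 that makes
#' the embedding isometric for the Fisher metric); it agrees with the metric
#' to second order and is an exact metric on the simplex. The `"arc"` form
#' 2 * acos(sum(sqrt(a * b))) is the geodesic (great-circle) distance; it
#' dominates the chord, with equality in the coincidence limit.
#'
#' @param a,b belief vectors of equal dimension.
#' @param form `"chord"` (default) or `"arc"`.
#' @return non-negative scalar distance (nats scale).
#' @export
information_distance <- function(a, b, form = c("chord", "arc")) {
  form <- match.arg(form)
  if (length(a) != length(b))
    stop("information_distance: dimension mismatch (", length(a), " vs ", length(b), ")")
  if (form == "chord") {
    2 * sqrt(sum((sqrt(a) - sqrt(b))^2))
  } else {
    2 * acos(min(1, max(-1, sum(sqrt(a * b)))))
  }
}

#' Information length of a discrete belief path
#'
#' Accumulates the information distance between consecutive points of a
#' belief trajectory. Returns an `info_path` object holding the points, the
#' per-step distances and their sum (the information length).
#'
#' @param points a list of belief vectors, or a matrix with one point per row.
#' @param form distance form passed to [information_distance()].
#' @return an object of class `info_path` with elements `points`
#'   (matrix, one row per point), `step_distances` and `total_length`.
#' @export
path_information_length <- function(points, form = c("chord", "arc")) {
  form <- match.arg(form)
  if (is.list(points)) points <- do.call(rbind, points)
  if (!is.matrix(points) || nrow(points) < 1L)
    stop("path_information_length: need at least one point")
  n <- nrow(points)
  steps <- if (n > 1L) {
    vapply(seq_len(n - 1L), function(i)
      information_distance(points[i, ], points[i + 1L, ], form), numeric(1))
  } else numeric(0)
  structure(list(points = points, step_distances = steps,
                 total_length = sum(steps), form = form),
            class = "info_path")
}

#' @export
print.info_path <- function(x, ...) {
  cat("<info_path> ", nrow(x$points), " points, ", length(x$step_distances),
      " steps, total length ", format(x$total_length, digits = 6),
      " (", x$form, ")\n", sep = "")
  invisible(x)
}

#' Geodesic (Fisher-Rao) distance between two categorical beliefs
#'
#' Shorthand for the `"arc"` form of [information_distance()].
#'
#' @inheritParams information_distance
#' @export
geodesic_distance <- function(a, b) information_distance(a, b, form = "arc")

#' Geodesic path between two interior beliefs
#'
#' Maps the endpoints to the positive orthant of the unit sphere by
#' componentwise square root, interpolates along the great circle in `k`
#' equal arcs, and squares back onto the simplex. Endpoints are returned
#' exactly.
#'
#' @param a,b interior belief vectors of equal dimension.
#' @param k number of interpolation arcs (the path has `k + 1` points).
#' @return a `(k + 1) x n` matrix of belief vectors, first row `a`, last `b`.
#' @export
geodesic_path <- function(a, b, k = 64L) {
  if (length(a) != length(b))
    stop("geodesic_path: dimension mismatch")
  a <- as_belief(a); b <- as_belief(b)
  ra <- sqrt(a); rb <- sqrt(b)
  th <- acos(min(1, max(-1, sum(ra * rb))))
  t <- seq(0, 1, length.out = k + 1L)
  if (th < 1e-12) {
    out <- matrix(rep(a, each = k + 1L), nrow = k + 1L)
  } else {
    # slerp on the unit sphere; positive-orthant endpoints are never antipodal
    w1 <- sin((1 - t) * th) / sin(th)
    w2 <- sin(t * th) / sin(th)
    emb <- outer(w1, ra) + outer(w2, rb)
    out <- emb^2
    out <- out / rowSums(out)
  }
  out[1L, ] <- a
  out[k + 1L, ] <- b
  out
}
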