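# POMDP generative-model containers, validation, Dirichlet learning of the
# likelihood (A) and transition (B) mappings, and JSON serialisation.

#' Construct a POMDP generative model
#'
#' The generative model P(o, s) of a discrete sequential decision task:
#' a likelihood matrix `A` (outcomes x states, columns sum to one), one
#' column-stochastic transition matrix per action in `B`, a log-preference
#' vector `C` over outcomes (unnormalised, nats; preferences enter planning
#' through `softmax(C)`), a prior belief `D` over initial states, and a
#' policy matrix (one row per policy, one column per time step, entries are
#' action indices). `factors` optionally records a factorisation of the
#' state space: `sizes`, an integer vector with `prod(sizes) == n_states`
#' (states are indexed with the first factor varying fastest, as in an R
#' array), and `static`, a logical vector marking factors whose state never
#' changes within a trial (used for retrospective learning).
#'
#' @param A likelihood matrix, `n_outcomes x n_states`.
#' @param B list of `n_states x n_states` transition matrices, one per action.
#' @param C numeric log-preference vector over outcomes.
#' @param D belief vector over initial states.
#' @param policies integer matrix of action sequences (policies x horizon).
#' @param labels optional list with character vectors `states`, `outcomes`,
#'   `actions`.
#' @param factors optional list with `sizes` and `static` as described above.
#' @return an object of class `pomdp_model`.
#' @export
pomdp_model <- function(A, B, C, D, policies, labels = NULL, factors = NULL) {
  if (is.vector(policies)) policies <- matrix(policies, nrow = 1L)
  m <- structure(list(A = A, B = B, C = C, D = D,
                      policies = policies, labels = labels, factors = factors),
                 class = "pomdp_model")
  v <- validate_model(m)
  if (length(v) > 0L)
    stop("invalid POMDP model:\n  ", paste(v, collapse = "\n  "))
  m
}

#' @export
print.pomdp_model <- function(x, ...) {
  cat("<pomdp_model> ", ncol(x$A), " states, ", nrow(x$A), " outcomes, ",
      length(x$B), " actions, ", nrow(x$policies), " policies of length ",
      ncol(x$policies), "\n", sep = "")
  if (!is.null(x$factors))
    cat("  state factors: ", paste(x$factors$sizes, collapse = " x "),
        " (static: ", paste(which(x$factors$static), collapse = ","), ")\n",
        sep = "")
  invisible(x)
}

#' Validate a POMDP model
#'
#' Checks the stochastic-matrix and policy invariants and reports each
#' violation as a human-readable string; an empty character vector means the
#' model is valid. Never throws.
#'
#' @param m a list or `pomdp_model` with elements `A`, `B`, `C`, `D`,
#'   `policies`.
#' @param tol tolerance on column sums.
#' @return character vector of violations (possibly empty).
#' @export
validate_model <- function(m, tol = 1e-10) {
  out <- character(0)
  chk_stoch <- function(M, name) {
    v <- character(0)
    if (any(M < 0))
      v <- c(v, paste0(name, ": negative entries in column(s) ",
                       paste(unique(which(M < 0, arr.ind = TRUE)[, 2]), collapse = ",")))
    cs <- colSums(M)
    bad <- which(abs(cs - 1) > tol)
    if (length(bad))
      v <- c(v, paste0(name, ": column(s) ", paste(bad, collapse = ","),
                       " do not sum to 1"))
    v
  }
  n_states <- ncol(m$A)
  out <- c(out, chk_stoch(m$A, "A"))
  for (i in seq_along(m$B)) {
    Bi <- m$B[[i]]
    if (!all(dim(Bi) == c(n_states, n_states)))
      out <- c(out, paste0("B[[", i, "]]: wrong dimensions"))
    else out <- c(out, chk_stoch(Bi, paste0("B[[", i, "]]")))
  }
  if (length(m$C) != nrow(m$A))
    out <- c(out, "C: length differs from number of outcomes")
  dv <- tryCatch({ as_belief(m$D); NULL }, error = function(e) conditionMessage(e))
  if (!is.null(dv)) out <- c(out, paste0("D: ", dv))
  if (length(m$D) != n_states)
    out <- c(out, "D: length differs from number of states")
  p <- m$policies
  if (is.null(dim(p)) || ncol(p) < 1L)
    out <- c(out, "policies: need at least one action per policy")
  else {
    if (any(p < 1L | p > length(m$B)))
      out <- c(out, "policies: action index out of range")
  }
  if (!is.null(m$factors) && prod(m$factors$sizes) != n_states)
    out <- c(out, "factors: prod(sizes) differs from number of states")
  out
}

#' Dirichlet concentration counts over A and B
#'
#' Holds the agent's Dirichlet posterior over the likelihood and transition
#' mappings. "Known" mappings are represented by large counts (the builders
#' use 1e4 times the true matrix); learnable mappings start at a flat
#' `prior_count` per plausible entry.
#'
#' @param a non-negative matrix shaped like the model's `A`.
#' @param b list of non-negative matrices shaped like the model's `B`.
#' @param prior_count positive floor on counts.
#' @return an object of class `dirichlet_counts`.
#' @export
dirichlet_counts <- function(a, b, prior_count = 1) {
  if (prior_count <= 0) stop("prior_count must be positive")
  structure(list(a = a, b = b, prior_count = prior_count),
            class = "dirichlet_counts")
}

#' @export
print.dirichlet_counts <- function(x, ...) {
  cat("<dirichlet_counts> a: ", nrow(x$a), "x", ncol(x$a), ", ",
      length(x$b), " transition arrays, total mass ",
      format(sum(x$a), digits = 6), " (a)\n", sep = "")
  invisible(x)
}

#' Expected log-parameters under Dirichlet counts
#'
#' Returns the Dirichlet expectation of the log parameters,
#' `digamma(count) - digamma(column sum)`, for the likelihood and each
#' transition array. Values are clamped below at `log(PROB_FLOOR)` so the
#' result is finite and commensurate with the package's probability floor.
#'
#' @param d a `dirichlet_counts` object.
#' @return list with `lnA` (matrix) and `lnB` (list of matrices).
#' @export
expected_log_params <- function(d) {
  elog <- function(M) {
    out <- digamma(M) - rep(digamma(colSums(M)), each = nrow(M))
    pmax(out, log(PROB_FLOOR))
  }
  list(lnA = elog(d$a), lnB = lapply(d$b, elog))
}

#' Mean parameters under Dirichlet counts
#'
#' Column-normalised counts: the posterior mean of the likelihood and
#' transition matrices. Used for forward prediction and policy rollouts.
#'
#' @param d a `dirichlet_counts` object.
#' @return list with `A` (matrix) and `B` (list of matrices).
#' @export
mean_params <- function(d) {
  norm <- function(M) sweep(M, 2, colSums(M), "/")
  list(A = norm(d$a), B = lapply(d$b, norm))
}

#' Accumulate Dirichlet counts from one observed transition
#'
#' Adds `rate * s_post` to the observed outcome's row of the likelihood
#' counts and `rate * (s_post %o% s_prev)` to the executed action's
#' transition counts. With delta beliefs this reduces to unit count
#' increments on the observed contingency.
#'
#' @param d a `dirichlet_counts` object.
#' @param o observed outcome index.
#' @param s_post posterior belief over states at the current step.
#' @param s_prev posterior belief at the previous step (used for `b`).
#'   Pass `NULL` to update only the likelihood counts.
#' @param action index of the executed action (ignored when `s_prev` is
#'   `NULL`).
#' @param rate non-negative learning rate.
#' @return the updated `dirichlet_counts` object.
#' @export
update_counts <- function(d, o, s_post, s_prev = NULL, action = NULL, rate = 1) {
  if (o < 1L || o > nrow(d$a)) stop("update_counts: outcome index out of range")
  if (rate < 0) stop("update_counts: rate must be non-negative")
  d$a[o, ] <- d$a[o, ] + rate * s_post
  if (!is.null(s_prev)) {
    if (is.null(action) || action < 1L || action > length(d$b))
      stop("update_counts: action index out of range")
    d$b[[action]] <- d$b[[action]] + rate * (s_post %o% s_prev)
  }
  d
}

#' Serialise a POMDP model to JSON
#'
#' Writes the model as a named-array JSON document with explicit shape
#' fields so tasks are inspectable and reproducible bit-exactly.
#'
#' @param m a `pomdp_model`.
#' @param path file path; when `NULL` the JSON string is returned.
#' @export
model_to_json <- function(m, path = NULL) {
  doc <- list(
    n_states = ncol(m$A), n_outcomes = nrow(m$A), n_actions = length(m$B),
    A = list(shape = dim(m$A), data = as.vector(t(m$A))),
    B = lapply(m$B, function(Bi) list(shape = dim(Bi), data = as.vector(t(Bi)))),
    C = m$C, D = m$D,
    policies = list(shape = dim(m$policies), data = as.vector(t(m$policies))),
    labels = m$labels, factors = m$factors)
  json <- jsonlite::toJSON(doc, digits = NA, auto_unbox = TRUE, null = "null")
  if (is.null(path)) return(json)
  writeLines(json, path)
  invisible(path)
}

#' Deserialise a POMDP model from JSON
#'
#' @param path file path or JSON string produced by [model_to_json()].
#' @return a `pomdp_model`.
#' @export
model_from_json <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = TRUE,
                            simplifyDataFrame = FALSE, simplifyMatrix = FALSE)
  unpack <- function(x) matrix(as.numeric(x$data),
                               nrow = x$shape[[1]], byrow = TRUE)
  factors <- doc$factors
  if (!is.null(factors)) {
    factors$sizes <- as.integer(factors$sizes)
    factors$static <- as.logical(factors$static)
  }
  policies <- unpack(doc$policies)
  storage.mode(policies) <- "integer"
  pomdp_model(A = unpack(doc$A),
              B = lapply(doc$B, unpack),
              C = as.numeric(doc$C), D = as.numeric(doc$D),
              policies = policies,
              labels = doc$labels, factors = factors)
}
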