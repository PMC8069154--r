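# Planning as inference (expected free energy), action selection, and the
# per-trial agent loop: observe -> infer states -> evaluate policies ->
# act -> (at trial end) learn.

sample_categorical <- function(p) {
  sample.int(length(p), 1L, prob = p)
}

#' Agent-side parameters derived from Dirichlet counts
#'
#' Precomputes everything policy evaluation and inference need from the
#' agent's counts: the expected log-likelihood (digamma form) used as
#' observation evidence, the mean likelihood and transitions used for
#' prediction and rollouts, the per-state outcome entropy (ambiguity), and
#' the per-state expected Dirichlet novelty (the information gain about
#' the likelihood parameters afforded by sampling each state; essentially
#' zero for known, high-count mappings).
#'
#' @param counts a `dirichlet_counts` object.
#' @return list with `lnA`, `A`, `B`, `ambiguity`, `novelty`.
#' @export
agent_params <- function(counts) {
  el <- expected_log_params(counts)
  mp <- mean_params(counts)
  Abar <- mp$A
  amb <- -colSums(Abar * log(pmax(Abar, PROB_FLOOR)))
  # structurally impossible entries (vanishing counts) carry no novelty
  W <- 0.5 * (1 / counts$a - rep(1 / colSums(counts$a), each = nrow(counts$a)))
  W[counts$a < 1e-2] <- 0
  nov <- colSums(Abar * W)
  list(lnA = el$lnA, A = Abar, B = mp$B, ambiguity = amb, novelty = nov)
}

#' Expected free energy of a policy
#'
#' Scores an action sequence from the current belief by rolling predicted
#' states forward through the transition model and accumulating, per step,
#' risk (KL divergence of predicted outcomes from the preference
#' distribution `softmax(C)`) plus ambiguity (expected outcome entropy
#' under the predicted states), minus - when the agent's Dirichlet counts
#' are supplied via `params` - the expected novelty of the likelihood
#' mapping, which draws the agent towards contingencies it has not yet
#' learned. Lower is better.
#'
#' @param m a `pomdp_model`.
#' @param s current belief over states.
#' @param policy integer vector of action indices.
#' @param params optional precomputed [agent_params()]; when `NULL` the
#'   model's own matrices are used and the novelty term is zero.
#' @return scalar expected free energy (nats).
#' @export
expected_free_energy <- function(m, s, policy, params = NULL) {
  if (is.null(params)) {
    Abar <- m$A
    Blist <- m$B
    amb <- -colSums(Abar * log(pmax(Abar, PROB_FLOOR)))
    nov <- rep(0, ncol(Abar))
  } else {
    Abar <- params$A; Blist <- params$B
    amb <- params$ambiguity; nov <- params$novelty
  }
  cpref <- softmax(m$C)
  G <- 0
  sp <- s
  for (a in policy) {
    sp <- as.vector(Blist[[a]] %*% sp)
    op <- as.vector(Abar %*% sp)
    risk <- sum(op * (log(pmax(op, PROB_FLOOR)) - log(pmax(cpref, PROB_FLOOR))))
    G <- G + risk + sum(sp * amb) - sum(sp * nov)
  }
  G
}

#' Evaluate a set of policies and select an action
#'
#' Computes the expected free energy of each policy, the softmax policy
#' posterior `softmax(-G)`, and the deterministically chosen action: the
#' first action of a policy attaining the minimal G (ties resolved to the
#' lowest policy index).
#'
#' @param m a `pomdp_model`.
#' @param s current belief.
#' @param policies integer matrix, one policy per row (defaults to the
#'   model's policy set).
#' @param params optional [agent_params()].
#' @return an object of class `policy_evaluation` with `G`,
#'   `policy_posterior`, `chosen_action`, `chosen_policy`.
#' @export
evaluate_policies <- function(m, s, policies = m$policies, params = NULL) {
  G <- apply(policies, 1L, function(p) expected_free_energy(m, s, p, params))
  best <- which.min(G)
  structure(list(G = G,
                 policy_posterior = softmax(-G),
                 chosen_action = policies[best, 1L],
                 chosen_policy = best),
            class = "policy_evaluation")
}

#' @export
print.policy_evaluation <- function(x, ...) {
  cat("<policy_evaluation> ", length(x$G), " policies, chosen action ",
      x$chosen_action, " (policy ", x$chosen_policy, ", G = ",
      format(min(x$G), digits = 6), ")\n", sep = "")
  invisible(x)
}

# Retrospective (smoothed) per-step posteriors for learning: for factors
# whose state is constant within a trial, the filtered marginal at each
# step is replaced by the end-of-trial marginal (exact up to the mean-field
# recombination, since a static factor's final posterior incorporates all
# of the trial's evidence); the joint is rebuilt as the product of factor
# marginals. Without factor metadata the filtered beliefs are returned.
smooth_static_factors <- function(model, beliefs) {
  f <- model$factors
  if (is.null(f) || !any(f$static)) return(beliefs)
  sizes <- f$sizes
  marg <- function(s) {
    arr <- array(s, dim = sizes)
    lapply(seq_along(sizes), function(k) as.vector(apply(arr, k, sum)))
  }
  final <- marg(beliefs[nrow(beliefs), ])
  out <- beliefs
  for (i in seq_len(nrow(beliefs))) {
    mg <- marg(beliefs[i, ])
    mg[f$static] <- final[f$static]
    out[i, ] <- as.vector(Reduce(`%o%`, mg))
  }
  out
}

#' Run one trial of the agent loop
#'
#' Executes the per-trial sequence: sample an observation from the
#' environment's true state through the true likelihood; infer hidden
#' states by the chosen scheme; evaluate the policies consistent with the
#' actions executed so far and perform the action with the lowest expected
#' free energy; and, after the final observation, update the Dirichlet
#' counts from the trial's (retrospectively smoothed) posteriors. The
#' trial's information length is the sum of the information lengths of all
#' inference steps.
#'
#' @param env a `task_environment` (see [build_tmaze()],
#'   [build_rule_surrogate()]).
#' @param counts the agent's current `dirichlet_counts`.
#' @param true_state index of the environment's true initial state.
#' @param scheme inference scheme passed to [run_inference()].
#' @param epsilon step size.
#' @param seed integer seed; mandatory, for reproducibility.
#' @param init `"prior"` starts each inference at the predictive prior;
#'   `"uniform"` at the mid-simplex point.
#' @param distance information-distance form.
#' @param learn apply Dirichlet learning at trial end.
#' @param learning_rate count increment per observation.
#' @param max_iter,tol passed to [run_inference()].
#' @param record_traces keep the full `inference_trace` of every step.
#' @return an object of class `trial_record`: `observations`, `actions`,
#'   `info_length`, `step_lengths`, `G` (list of per-decision G vectors),
#'   `beliefs` (matrix of per-step posteriors), `counts` (updated),
#'   `final_true_state`, and optionally `traces`.
#' @export
run_trial <- function(env, counts, true_state,
                      scheme = c("active_inference", "natural_gradient"),
                      epsilon = 0.25, seed = NULL,
                      init = c("prior", "uniform"),
                      distance = c("chord", "arc"),
                      learn = TRUE, learning_rate = 1,
                      max_iter = 64L, tol = 1e-4,
                      record_traces = FALSE) {
  scheme <- match.arg(scheme)
  init <- match.arg(init)
  distance <- match.arg(distance)
  if (is.null(seed)) stop("run_trial requires an explicit integer seed")
  set.seed(seed)
  m <- env$model
  Tn <- env$horizon
  n <- ncol(m$A)
  par <- agent_params(counts)
  obs <- integer(Tn + 1L)
  acts <- integer(Tn)
  step_lengths <- numeric(Tn + 1L)
  beliefs <- matrix(NA_real_, Tn + 1L, n)
  Gs <- vector("list", Tn)
  traces <- if (record_traces) vector("list", Tn + 1L) else NULL
  s_prev <- m$D
  true <- true_state
  for (t in seq_len(Tn + 1L)) {
    obs[t] <- sample_categorical(m$A[, true])
    log_prior <- if (t == 1L) log(floor_beliefs(m$D))
                 else log(floor_beliefs(as.vector(par$B[[acts[t - 1L]]] %*% s_prev)))
    ctx <- fe_context(par$lnA[obs[t], ], log_prior)
    s0 <- if (init == "uniform") rep(1 / n, n) else softmax(log_prior)
    tr <- run_inference(s0, ctx, scheme, epsilon, max_iter, tol, distance)
    s_t <- tr$beliefs[nrow(tr$beliefs), ]
    beliefs[t, ] <- s_t
    step_lengths[t] <- tr$info_path$total_length
    if (record_traces) traces[[t]] <- tr
    if (t <= Tn) {
      cand <- m$policies
      if (t > 1L) {
        ok <- rowSums(cand[, seq_len(t - 1L), drop = FALSE] !=
                        matrix(acts[seq_len(t - 1L)], nrow(cand), t - 1L,
                               byrow = TRUE)) == 0L
        cand <- cand[ok, , drop = FALSE]
      }
      remaining <- cand[, t:Tn, drop = FALSE]
      pe <- evaluate_policies(m, s_t, remaining, par)
      Gs[[t]] <- pe$G
      acts[t] <- pe$chosen_action
      true <- sample_categorical(m$B[[acts[t]]][, true])
    }
    s_prev <- s_t
  }
  if (learn) {
    sm <- smooth_static_factors(m, beliefs)
    for (t in seq_len(Tn + 1L)) {
      counts <- update_counts(counts, obs[t], sm[t, ],
                              s_prev = if (t > 1L) sm[t - 1L, ] else NULL,
                              action = if (t > 1L) acts[t - 1L] else NULL,
                              rate = learning_rate)
    }
  }
  structure(list(observations = obs, actions = acts,
                 info_length = sum(step_lengths),
                 step_lengths = step_lengths,
                 G = Gs, beliefs = beliefs, counts = counts,
                 final_true_state = true, scheme = scheme,
                 traces = traces),
            class = "trial_record")
}

#' @export
print.trial_record <- function(x, ...) {
  cat("<trial_record> observations ", paste(x$observations, collapse = ","),
      "; actions ", paste(x$actions, collapse = ","),
      "; information length ", format(x$info_length, digits = 6), "\n",
      sep = "")
  invisible(x)
}

#' Export a trial record as JSON
#'
#' @param rec a `trial_record`.
#' @param path file path; when `NULL` the JSON string is returned.
#' @export
trial_to_json <- function(rec, path = NULL) {
  doc <- list(observations = rec$observations, actions = rec$actions,
              info_length = rec$info_length, step_lengths = rec$step_lengths,
              G = rec$G)
  json <- jsonlite::toJSON(doc, digits = NA, auto_unbox = TRUE)
  if (is.null(path)) return(json)
  writeLines(json, path)
  invisible(path)
}
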