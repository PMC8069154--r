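# Task builders: the T-Maze foraging paradigm and a dimensionally faithful
# abstract-rule surrogate. Both return a `task_environment`: the true
# generative model, the agent's prior Dirichlet counts (large counts for
# known mappings, flat counts for the contingencies to be learned), the
# trial horizon and a schedule function drawing the per-trial true initial
# states (using the current RNG state, so callers must seed).

KNOWN_COUNT <- 1e4       # Dirichlet mass representing a known mapping
STRUCT_ZERO <- 1e-6      # count floor for structurally impossible entries

task_environment <- function(model, counts, horizon, task, schedule) {
  structure(list(model = model, counts = counts, horizon = horizon,
                 task = task, schedule = schedule),
            class = "task_environment")
}

#' @export
print.task_environment <- function(x, ...) {
  cat("<task_environment> ", x$task, ", horizon ", x$horizon, "\n", sep = "")
  print(x$model)
  invisible(x)
}

# ---- T-Maze ---------------------------------------------------------------

# State factors: location {centre, left arm, right arm, cue} x context
# {reward-left, reward-right}; joint index = loc + 4 * (ctx - 1).
tmaze_state <- function(loc, ctx) loc + 4L * (ctx - 1L)

#' Build the T-Maze task
#'
#' A two-step maze: the agent starts at the centre; the reward sits in the
#' left or right upper arm (the context); the bottom arm holds a cue that
#' reveals the context. Eight joint hidden states (4 locations x 2
#' contexts, a seven-dimensional belief simplex), four actions (move to
#' centre / left arm / right arm / cue; the upper arms are absorbing) and
#' seven outcomes (centre; each arm with or without the reward; the two cue
#' messages). Preferences favour the reward and penalise the unbaited arm.
#' The prior `D` knows the start location and is uniform over contexts.
#'
#' The agent's likelihood counts are large (known) everywhere except the
#' two centre-location columns, which start flat: the ambient start-of-trial
#' observation thereby accumulates context-correlated evidence across
#' trials, which is how the agent can come to treat a constant reward
#' location as known before visiting the cue.
#'
#' @param reward_value log-preference (nats) for reward outcomes.
#' @param punish_value log-preference (nats, non-positive) for the unbaited
#'   arm.
#' @return a `task_environment` with horizon 2 and the 16 raw two-step
#'   policies.
#' @export
build_tmaze <- function(reward_value = 3, punish_value = -6) {
  n_s <- 8L; n_o <- 7L; n_a <- 4L
  # outcomes: 1 centre, 2 left+reward, 3 left-null, 4 right+reward,
  #           5 right-null, 6 cue-says-left, 7 cue-says-right
  A <- matrix(0, n_o, n_s)
  out_at <- function(loc, ctx) {
    if (loc == 1L) 1L
    else if (loc == 2L) if (ctx == 1L) 2L else 3L
    else if (loc == 3L) if (ctx == 2L) 4L else 5L
    else if (ctx == 1L) 6L else 7L
  }
  for (loc in 1:4) for (ctx in 1:2)
    A[out_at(loc, ctx), tmaze_state(loc, ctx)] <- 1
  B <- lapply(1:4, function(a) {
    Ba <- matrix(0, n_s, n_s)
    for (loc in 1:4) for (ctx in 1:2) {
      dest <- if (loc %in% c(2L, 3L)) loc else a   # upper arms absorb
      Ba[tmaze_state(dest, ctx), tmaze_state(loc, ctx)] <- 1
    }
    Ba
  })
  C <- c(0, reward_value, punish_value, reward_value, punish_value, 0, 0)
  D <- rep(0, n_s)
  D[tmaze_state(1L, 1L)] <- 0.5
  D[tmaze_state(1L, 2L)] <- 0.5
  policies <- as.matrix(expand.grid(a1 = 1:4, a2 = 1:4))
  dimnames(policies) <- NULL
  labels <- list(
    states = paste(rep(c("centre", "left", "right", "cue"), 2),
                   rep(c("reward-left", "reward-right"), each = 4), sep = "/"),
    outcomes = c("centre", "left+reward", "left-null", "right+reward",
                 "right-null", "cue-left", "cue-right"),
    actions = c("go-centre", "go-left", "go-right", "go-cue"))
  m <- pomdp_model(A, B, C, D, policies, labels,
                   factors = list(sizes = c(4L, 2L), static = c(FALSE, TRUE)))
  a0 <- KNOWN_COUNT * A + STRUCT_ZERO
  a0[, c(tmaze_state(1L, 1L), tmaze_state(1L, 2L))] <- 1   # centre columns flat
  b0 <- lapply(B, function(Ba) KNOWN_COUNT * Ba + STRUCT_ZERO)
  counts <- dirichlet_counts(a0, b0, prior_count = STRUCT_ZERO)
  task_environment(m, counts, horizon = 2L, task = "tmaze",
                   schedule = function(n_trials) {
                     ctx <- tmaze_schedule(n_trials)
                     list(states = tmaze_state(1L, ctx), context = ctx)
                   })
}

#' Per-trial context schedule of the T-Maze
#'
#' The reward's location is drawn uniformly at random for the first three
#' trials; from the fourth trial onwards it is drawn once and held constant.
#' Uses the current RNG state: seed before calling.
#'
#' @param n_trials number of trials.
#' @param n_random number of initial random-context trials (default 3).
#' @return integer vector of contexts (1 = reward-left, 2 = reward-right).
#' @export
tmaze_schedule <- function(n_trials, n_random = 3L) {
  if (n_trials < 0L) stop("tmaze_schedule: n_trials must be non-negative")
  k <- min(n_random, n_trials)
  ctx <- sample.int(2L, k, replace = TRUE)
  if (n_trials > k) ctx <- c(ctx, rep(sample.int(2L, 1L), n_trials - k))
  ctx
}

# ---- Abstract-rule surrogate ----------------------------------------------

# State factors: rule (static) x stimulus (static within a trial) x gaze x
# report; joint index with the first factor varying fastest. Actions set
# (gaze, report). This is a dimensional surrogate for published abstract
# rule-learning generative models - it matches their printed dimensions (16
# control states, 144 hidden states, 48 outcomes) but not their exact
# contingencies.
rule_state <- function(r, s, g, p, sizes) {
  r + sizes[1] * (s - 1L) + sizes[1] * sizes[2] * (g - 1L) +
    sizes[1] * sizes[2] * sizes[3] * (p - 1L)
}

rule_action <- function(g, p, sizes) g + sizes[3] * (p - 1L)

# correct report option (1-based among the sizes[2] report choices)
rule_answer <- function(s, r, n) ((s + r - 2L) %% n) + 1L

#' Build the abstract-rule surrogate task
#'
#' A rule-learning paradigm: each trial presents a stimulus; a latent rule
#' (fixed across an agent's trials) determines the unique correct response;
#' the agent may inspect the stimulus and a rule cue before a forced guess,
#' upon which it receives correct/incorrect feedback. State factors are
#' rule (3) x stimulus (3) x gaze (4: fixation, stimulus, rule cue, rest)
#' x report (4: none + 3 responses), giving 144 joint hidden states (a
#' 143-dimensional belief simplex); actions set (gaze, report) jointly, 16
#' control states; outcomes factor as percept (4) x feedback (3) x gaze
#' echo (4), 48 in total. Preferences favour correct and penalise
#' incorrect feedback.
#'
#' The agent's counts are flat over the rule-cue percepts (it must learn
#' what the cue means) and over the ambient fixation percept (the channel
#' through which rule statistics accumulate across trials); everything else
#' is known. The policy set is the task's observe-observe-respond
#' repertoire: two free gaze steps followed by a forced guess (48
#' policies, horizon 3).
#'
#' @param factor_sizes integer vector (rule, stimulus, gaze, report);
#'   default `c(3, 3, 4, 4)`.
#' @param n_outcomes total outcome count; must equal
#'   `(max(rule, stimulus) + 1) * 3 * gaze` (default 48).
#' @param reward_value,punish_value log-preferences for correct/incorrect
#'   feedback.
#' @return a `task_environment` with horizon 3.
#' @export
build_rule_surrogate <- function(factor_sizes = c(3L, 3L, 4L, 4L),
                                 n_outcomes = 48L,
                                 reward_value = 3, punish_value = -6) {
  sz <- as.integer(factor_sizes)
  if (length(sz) != 4L) stop("factor_sizes must have four entries")
  R <- sz[1]; S <- sz[2]; Gz <- sz[3]; Rp <- sz[4]
  if (Rp < S + 1L) stop("need at least one report option per stimulus plus 'none'")
  n_s <- prod(sz)
  n_p <- max(R, S) + 1L                 # percepts: blank + symbols
  if (n_p * 3L * Gz != n_outcomes)
    stop("inconsistent sizes: (max(rule, stimulus) + 1) * 3 * gaze must equal n_outcomes")
  n_a <- Gz * Rp
  out_id <- function(percept, fb, g) percept + n_p * (fb - 1L) + n_p * 3L * (g - 1L)
  A <- matrix(0, n_outcomes, n_s)
  for (r in 1:R) for (s in 1:S) for (g in 1:Gz) for (p in 1:Rp) {
    percept <- if (g == 2L) 1L + s else if (g == 3L) 1L + r else 1L
    fb <- if (p == 1L) 1L else if ((p - 1L) == rule_answer(s, r, S)) 2L else 3L
    A[out_id(percept, fb, g), rule_state(r, s, g, p, sz)] <- 1
  }
  B <- lapply(seq_len(n_a), function(a) {
    g_to <- ((a - 1L) %% Gz) + 1L
    p_to <- ((a - 1L) %/% Gz) + 1L
    Ba <- matrix(0, n_s, n_s)
    for (r in 1:R) for (s in 1:S) for (g in 1:Gz) for (p in 1:Rp)
      Ba[rule_state(r, s, g_to, p_to, sz), rule_state(r, s, g, p, sz)] <- 1
    Ba
  })
  C <- rep(0, n_outcomes)
  for (g in 1:Gz) for (percept in 1:n_p) {
    C[out_id(percept, 2L, g)] <- reward_value
    C[out_id(percept, 3L, g)] <- punish_value
  }
  D <- rep(0, n_s)
  for (r in 1:R) for (s in 1:S)
    D[rule_state(r, s, 1L, 1L, sz)] <- 1 / (R * S)
  # policies: gaze freely twice (no report), then a forced guess at fixation
  pol <- expand.grid(g1 = 1:Gz, g2 = 1:Gz, guess = 2:Rp)
  policies <- cbind(rule_action(pol$g1, 1L, sz),
                    rule_action(pol$g2, 1L, sz),
                    rule_action(1L, pol$guess, sz))
  dimnames(policies) <- NULL
  labels <- list(
    outcomes = NULL, states = NULL,
    actions = paste0("gaze", rep(1:Gz, Rp), "/report", rep(1:Rp, each = Gz) - 1L))
  m <- pomdp_model(A, B, C, D, policies, labels,
                   factors = list(sizes = sz,
                                  static = c(TRUE, TRUE, FALSE, FALSE)))
  a0 <- KNOWN_COUNT * A + STRUCT_ZERO
  # learnable: what the rule cue shows ...
  for (r in 1:R) for (s in 1:S) for (p in 1:Rp) {
    col <- rule_state(r, s, 3L, p, sz)
    fb <- if (p == 1L) 1L else if ((p - 1L) == rule_answer(s, r, S)) 2L else 3L
    a0[, col] <- STRUCT_ZERO
    a0[out_id(1L + (1:R), fb, 3L), col] <- 1
  }
  # ... and the ambient fixation percept
  for (r in 1:R) for (s in 1:S) {
    col <- rule_state(r, s, 1L, 1L, sz)
    a0[, col] <- STRUCT_ZERO
    a0[out_id(1:n_p, 1L, 1L), col] <- 1
  }
  b0 <- lapply(B, function(Ba) KNOWN_COUNT * Ba + STRUCT_ZERO)
  counts <- dirichlet_counts(a0, b0, prior_count = STRUCT_ZERO)
  task_environment(m, counts, horizon = 3L, task = "rule",
                   schedule = function(n_trials) {
                     r <- sample.int(R, 1L)
                     s <- sample.int(S, n_trials, replace = TRUE)
                     list(states = rule_state(r, s, 1L, 1L, sz),
                          rule = r, stimuli = s)
                   })
}

#' Build a task environment from a YAML config
#'
#' Reads a YAML document with a `task` field (`"tmaze"` or `"rule"`) and
#' optional builder arguments (e.g. `reward_value`, `punish_value`,
#' `factor_sizes`) and calls the corresponding builder.
#'
#' @param path YAML file path.
#' @return a `task_environment`.
#' @export
task_from_yaml <- function(path) {
  cfg <- yaml::read_yaml(path)
  task <- match.arg(cfg$task, c("tmaze", "rule"))
  cfg$task <- NULL
  builder <- if (task == "tmaze") build_tmaze else build_rule_surrogate
  do.call(builder, cfg)
}
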