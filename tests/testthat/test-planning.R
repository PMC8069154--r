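test_that("policy evaluation yields a softmax posterior and argmin action with stable ties", {
  env <- build_tmaze()
  s <- env$model$D
  pe <- evaluate_policies(env$model, s)
  expect_equal(sum(pe$policy_posterior), 1, tolerance = 1e-12)
  expect_equal(pe$policy_posterior, softmax(-pe$G), tolerance = 1e-12)
  expect_equal(pe$chosen_action, env$model$policies[which.min(pe$G), 1])
  # exact ties resolve to the lowest policy index: a fully symmetric model
  n <- 3
  m <- pomdp_model(A = diag(n), B = list(diag(n), diag(n)), C = rep(0, n),
                   D = rep(1 / n, n), policies = rbind(c(1L, 1L), c(2L, 2L)))
  pe2 <- evaluate_policies(m, rep(1 / n, n))
  expect_equal(pe2$G[1], pe2$G[2], tolerance = 1e-12)
  expect_identical(pe2$chosen_policy, 1L)
})

test_that("expected free energy vanishes for uniform predictions under flat preferences", {
  # deterministic likelihood, uniform belief, uniform preferences:
  # predicted outcomes are uniform, ambiguity zero, so G = 0
  n <- 4
  perm <- diag(n)[, c(2, 3, 4, 1)]
  m <- pomdp_model(A = diag(n), B = list(perm), C = rep(0, n),
                   D = rep(1 / n, n), policies = matrix(1L, 1, 2))
  expect_equal(expected_free_energy(m, rep(1 / n, n), c(1L, 1L)), 0,
               tolerance = 1e-10)
})

test_that("the cue is epistemically preferred under flat preferences", {
  # with flat preferences, a policy that visits the context-revealing cue
  # has strictly lower expected free energy than one that stays put
  env <- build_tmaze(reward_value = 0, punish_value = 0)
  m <- env$model
  g_cue <- expected_free_energy(m, m$D, c(4L, 4L))
  g_stay <- expected_free_energy(m, m$D, c(1L, 1L))
  expect_lt(g_cue, g_stay)
})

test_that("with known context the reward arm is exploited", {
  env <- build_tmaze()
  m <- env$model
  for (ctx in 1:2) {
    s <- rep(0, 8); s[1 + 4 * (ctx - 1)] <- 1      # centre, context known
    pe <- evaluate_policies(m, floor_beliefs(s))
    arm <- if (ctx == 1) 2L else 3L
    expect_identical(pe$chosen_action, arm)
    # the arm is absorbing, so every continuation of it ties at the minimum
    g_arm <- pe$G[m$policies[, 1] == arm]
    expect_equal(diff(range(g_arm)), 0, tolerance = 1e-10)
  }
})

test_that("the trial loop observes, infers, plans, acts and learns coherently", {
  env <- build_tmaze()
  expect_error(run_trial(env, env$counts, true_state = 1L), "seed")
  rec <- run_trial(env, env$counts, true_state = 1L,
                   seed = 7L, init = "uniform", record_traces = TRUE)
  # with a fresh agent and unknown context, the first action visits the cue
  expect_identical(rec$actions[1], 4L)
  # trial information length is the sum of its steps' path lengths
  expect_equal(rec$info_length, sum(rec$step_lengths))
  expect_equal(rec$step_lengths,
               sapply(rec$traces, function(t) t$info_path$total_length))
  # deterministic model + seeded rng: observation sequence fully determined
  rec2 <- run_trial(env, env$counts, true_state = 1L, seed = 7L,
                    init = "uniform")
  expect_identical(rec2$observations, rec$observations)
  expect_identical(rec2$actions, rec$actions)
  # learning accumulated one unit of likelihood mass per observation
  expect_equal(sum(rec$counts$a - env$counts$a), length(rec$observations),
               tolerance = 1e-8)
  # cue observation pins the context: final belief concentrated on true ctx
  final <- rec$beliefs[nrow(rec$beliefs), ]
  ctx_marg <- sum(final[1:4])
  expect_gt(ctx_marg, 0.99)
})

test_that("relabelling left and right yields mirror-symmetric behaviour", {
  # state permutation swapping arms and contexts; outcome permutation
  # swapping the corresponding observations; action permutation swapping
  # the go-left / go-right controls
  env <- build_tmaze()
  m <- env$model
  loc_p <- c(1L, 3L, 2L, 4L)
  ps <- as.vector(outer(loc_p, c(2L, 1L), function(l, c) l + 4L * (c - 1L)))
  po <- c(1L, 4L, 5L, 2L, 3L, 7L, 6L)
  pa <- c(1L, 3L, 2L, 4L)
  expect_equal(m$A[po, ps], m$A, ignore_attr = TRUE)
  for (a in 1:4)
    expect_equal(m$B[[pa[a]]][ps, ps], m$B[[a]], ignore_attr = TRUE)
  expect_equal(m$C[po], m$C)
  expect_equal(m$D[ps], m$D)
  # consequently G is equivariant under the mirror (an involution):
  # mirrored beliefs with mirrored policies score identically
  set.seed(30)
  for (i in 1:5) {
    s <- rand_belief(8)
    pol <- sample(4, 2, replace = TRUE)
    expect_equal(expected_free_energy(m, s[ps], pa[pol]),
                 expected_free_energy(m, s, pol), tolerance = 1e-10)
  }
})

test_that("trial records serialise to JSON", {
  env <- build_tmaze()
  rec <- run_trial(env, env$counts, true_state = 5L, seed = 9L)
  f <- tempfile(fileext = ".json")
  trial_to_json(rec, f)
  doc <- jsonlite::fromJSON(f)
  expect_equal(doc$observations, rec$observations)
  expect_equal(doc$info_length, rec$info_length, tolerance = 1e-12)
  unlink(f)
})
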