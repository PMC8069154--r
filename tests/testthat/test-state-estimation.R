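test_that("both updates fix the exact posterior and reduce to identity at zero step", {
  set.seed(20)
  for (i in 1:20) {
    n <- sample(3:6, 1)
    ctx <- rand_ctx(n)
    post <- exact_posterior(ctx)
    s <- rand_belief(n)
    expect_equal(ai_update(post, ctx, 0.25), post, tolerance = 1e-12)
    expect_equal(ng_update(post, ctx, 0.25), post, tolerance = 1e-12)
    expect_equal(ai_update(s, ctx, 0), s, tolerance = 1e-12)
    expect_equal(ng_update(s, ctx, 0), s, tolerance = 1e-12)
    # the softmax update equals s * exp(-eps grad), renormalised
    g <- free_energy_gradient(s, ctx)
    w <- s * exp(-0.25 * g)
    expect_equal(ai_update(s, ctx, 0.25), w / sum(w), tolerance = 1e-12)
    # both updates stay exactly on the simplex
    for (eps in c(0.1, 0.25, 0.5)) {
      expect_equal(sum(ai_update(s, ctx, eps)), 1, tolerance = 1e-12)
      expect_equal(sum(ng_update(s, ctx, eps)), 1, tolerance = 1e-12)
      expect_true(all(ng_update(s, ctx, eps) >= 0))
    }
  }
})

test_that("the two schemes agree to first order in the step size", {
  # Richardson check: the discrepancy is O(eps^2), so halving eps should
  # shrink it about fourfold
  set.seed(21)
  ratios <- replicate(100, {
    n <- sample(3:6, 1)
    ctx <- rand_ctx(n)
    s <- rand_belief(n)
    d1 <- sqrt(sum((ai_update(s, ctx, 0.1) - ng_update(s, ctx, 0.1))^2))
    d2 <- sqrt(sum((ai_update(s, ctx, 0.05) - ng_update(s, ctx, 0.05))^2))
    d1 / d2
  })
  expect_gt(median(ratios), 3.5)
  expect_lt(median(ratios), 4.5)
  expect_gt(mean(ratios >= 3 & ratios <= 5), 0.8)
})

test_that("inference converges to the Bayes posterior with monotone free energy", {
  set.seed(22)
  for (i in 1:30) {
    ctx <- rand_ctx(3)
    s0 <- rand_belief(3)
    post <- exact_posterior(ctx)
    for (sch in c("active_inference", "natural_gradient")) {
      tr <- run_inference(s0, ctx, sch, epsilon = 0.25)
      sf <- tr$beliefs[nrow(tr$beliefs), ]
      expect_lt(total_variation(sf, post), 1e-3)
      # free energies non-increasing; terminal value is -ln P(o) + KL
      expect_true(all(diff(tr$free_energies) <= 1e-8))
      expect_equal(tr$free_energies[tr$iterations], free_energy(sf, ctx),
                   tolerance = 1e-12)
      # trajectory at least as long as the straight-line information distance
      expect_gte(tr$info_path$total_length,
                 information_distance(tr$beliefs[1, ], sf) - 1e-12)
      # recorded voltages are the log-belief code
      expect_equal(softmax(tr$voltages[tr$iterations, ]), sf, tolerance = 1e-10)
      expect_true(all(abs(rowSums(tr$beliefs) - 1) < 1e-10))
    }
  }
})

test_that("two-state problems reach the closed-form Bayes posterior under both schemes", {
  set.seed(23)
  for (i in 1:10) {
    lik <- runif(2, 0.05, 0.95); pri <- rand_belief(2)
    ctx <- fe_context(log(lik), log(pri))
    bayes <- lik * pri / sum(lik * pri)
    for (sch in c("active_inference", "natural_gradient")) {
      tr <- run_inference(c(0.5, 0.5), ctx, sch)
      expect_lt(total_variation(tr$beliefs[nrow(tr$beliefs), ], bayes), 1e-3)
    }
  }
})

test_that("the scheme discrepancy in information length shrinks with the step size", {
  set.seed(24)
  ctxs <- lapply(1:15, function(i) rand_ctx(4, 3))
  s0s <- lapply(1:15, function(i) rand_belief(4))
  md <- sapply(c(0.5, 0.25, 0.1), function(eps) {
    mean(mapply(function(ctx, s0) {
      a <- run_inference(s0, ctx, "active_inference", epsilon = eps,
                         max_iter = 512, tol = 1e-8)
      b <- run_inference(s0, ctx, "natural_gradient", epsilon = eps,
                         max_iter = 512, tol = 1e-8)
      abs(a$info_path$total_length - b$info_path$total_length)
    }, ctxs, s0s))
  })
  expect_true(all(diff(md) < 0))
})

test_that("simulated LFPs are voltage increments that decay at convergence", {
  set.seed(25)
  ctx <- rand_ctx(5)
  tr <- run_inference(rand_belief(5), ctx, "active_inference")
  l <- simulated_lfp(tr)
  expect_equal(nrow(l), tr$iterations - 1)
  expect_equal(l, diff(tr$voltages))
  expect_true(tr$converged)
  # depolarisations decay towards zero as the gradient vanishes
  first <- sqrt(sum(l[1, ]^2)); last <- sqrt(sum(l[nrow(l), ]^2))
  expect_lt(last, 1e-2)
  expect_lt(last, 0.05 * first)
  # starting at the posterior: immediate convergence, empty LFP
  tr0 <- run_inference(exact_posterior(ctx), ctx)
  expect_equal(nrow(simulated_lfp(tr0)), 0)
})

test_that("traces export to tidy CSV and reload consistently", {
  set.seed(26)
  tr <- run_inference(rand_belief(3), rand_ctx(3))
  f <- tempfile(fileext = ".csv")
  trace_to_csv(tr, f)
  df <- read.csv(f)
  expect_equal(nrow(df), 3 * tr$iterations)
  expect_equal(matrix(df$belief, ncol = 3, byrow = TRUE), tr$beliefs,
               ignore_attr = TRUE, tolerance = 1e-12)
  expect_equal(max(df$cumulative_information_length),
               tr$info_path$total_length, tolerance = 1e-12)
  unlink(f)
})
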