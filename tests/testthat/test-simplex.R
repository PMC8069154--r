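test_that("softmax maps potentials to the simplex and generalises the sigmoid", {
  expect_equal(softmax(c(0, 0, 0)), rep(1 / 3, 3))
  expect_equal(softmax(log(c(0.2, 0.3, 0.5))), c(0.2, 0.3, 0.5))
  # two-component softmax is the logistic sigmoid
  expect_equal(softmax(c(0, 0)), c(0.5, 0.5))
  for (v in c(-3, -0.7, 0.4, 2.5))
    expect_equal(softmax(c(v, 0)), c(stats::plogis(v), 1 - stats::plogis(v)))
  # shift invariance
  set.seed(1)
  for (i in 1:20) {
    v <- rnorm(5, 0, 3)
    expect_equal(softmax(v + rnorm(1, 0, 10)), softmax(v), tolerance = 1e-12)
    expect_equal(sum(softmax(v)), 1)
  }
  expect_error(softmax(c(1, NaN)), "finite")
  expect_error(softmax(c(1, Inf)), "finite")
})

test_that("inverse Fisher metric is diag(s) and acts as an elementwise product", {
  expect_equal(inverse_fisher_metric(rep(0.25, 4)), diag(0.25, 4))
  expect_equal(inverse_fisher_metric(c(0.5, 0.5)), diag(0.5, 2))
  set.seed(2)
  for (i in 1:20) {
    s <- rand_belief(sample(3:8, 1))
    u <- rnorm(length(s))
    expect_equal(as.vector(inverse_fisher_metric(s) %*% u), s * u,
                 tolerance = 1e-14)
  }
  expect_warning(inverse_fisher_metric(c(0, 0.5, 0.5)), "boundary")
})

test_that("information distance is a metric with the Fisher local form", {
  s <- c(0.1, 0.2, 0.7)
  expect_identical(information_distance(s, s), 0)
  expect_equal(information_distance(c(1, 0, 0), c(0, 1, 0)), 2 * sqrt(2))
  expect_error(information_distance(c(0.5, 0.5), c(1, 0, 0) / 1), "mismatch")
  set.seed(3)
  for (form in c("chord", "arc")) {
    for (i in 1:50) {
      n <- sample(3:6, 1)
      a <- rand_belief(n); b <- rand_belief(n); c <- rand_belief(n)
      dab <- information_distance(a, b, form)
      expect_gte(dab, 0)
      expect_equal(dab, information_distance(b, a, form))
      expect_lte(dab,
                 information_distance(a, c, form) + information_distance(c, b, form) + 1e-12)
    }
  }
  # chord <= arc, ratio -> 1 in the coincidence limit
  set.seed(4)
  a <- rand_belief(4)
  prev_ratio <- 0
  for (t in c(0.5, 0.05, 0.005)) {
    b <- floor_beliefs(a + t * (rand_belief(4) - a))
    ch <- information_distance(a, b); arc <- information_distance(a, b, "arc")
    expect_lte(ch, arc + 1e-14)
    ratio <- ch / arc
    expect_gte(ratio, prev_ratio)   # monotone approach to 1
    prev_ratio <- ratio
  }
  expect_gt(prev_ratio, 1 - 1e-4)
  # chord distance agrees with the quadratic form of the metric (the Hessian
  # of the KL divergence, diag(1/s)) to second order
  set.seed(5)
  for (i in 1:10) {
    u <- rand_belief(5)
    del <- (rand_belief(5) - u) * 1e-4
    quad <- sqrt(sum(del^2 / u))
    expect_equal(information_distance(u, floor_beliefs(u + del)) / quad, 1,
                 tolerance = 1e-2)
  }
})

test_that("path information length is additive and refines towards the arc length", {
  a <- c(0.8, 0.15, 0.05); b <- c(0.1, 0.1, 0.8); m <- c(1, 1, 1) / 3
  expect_equal(path_information_length(list(a))$total_length, 0)
  p3 <- path_information_length(list(a, m, b))
  expect_equal(p3$total_length,
               information_distance(a, m) + information_distance(m, b))
  expect_length(p3$step_distances, 2)
  # subdividing a straight simplex segment: length is monotone in the
  # refinement and, once fine, is no shorter than the endpoint geodesic
  seg <- function(k) t(sapply(seq(0, 1, length.out = k + 1),
                              function(t) (1 - t) * a + t * b))
  lens <- sapply(c(1, 2, 8, 64, 256), function(k)
    path_information_length(seg(k))$total_length)
  expect_true(all(diff(lens) >= -1e-12))
  expect_gte(lens[5], geodesic_distance(a, b) * (1 - 1e-3))
})

test_that("geodesics follow the sphere embedding", {
  a <- c(0.9, 0.1); b <- c(0.1, 0.9)
  g <- geodesic_path(a, b, k = 2)
  expect_equal(g[1, ], a)
  expect_equal(g[3, ], b)
  expect_equal(g[2, ], c(0.5, 0.5))                     # symmetric midpoint
  expect_equal(geodesic_path(a, a, k = 4),
               matrix(rep(a, each = 5), 5))             # constant path
  expect_error(geodesic_path(a, c(1, 0, 0) / 1), "mismatch")
  # discretised geodesic length approaches the arc distance from below
  set.seed(6)
  u <- rand_belief(5); v <- rand_belief(5)
  arc <- geodesic_distance(u, v)
  lens <- sapply(c(4, 16, 64, 256), function(k)
    path_information_length(geodesic_path(u, v, k))$total_length)
  expect_true(all(diff(lens) >= -1e-12))
  expect_equal(lens[4], arc, tolerance = 1e-4)
  expect_true(all(lens <= arc + 1e-12))
})

test_that("belief validation and flooring behave", {
  expect_error(as_belief(c(0.5, 0.6)), "sum to 1")
  expect_error(as_belief(c(1.2, -0.2)), "non-negative")
  expect_error(as_belief(0.5), "length")
  f <- floor_beliefs(c(1, 0, 0))
  expect_true(all(f > 0))
  expect_equal(sum(f), 1)
})
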