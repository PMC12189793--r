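test_that("linear segment cost matches hand OLS and its degenerate cases", {
  # y = (0,1,0) on x = (1,2,3): flat line at 1/3, RSS = 1/9 + 4/9 + 1/9
  expect_equal(linear_segment_cost(c(0, 1, 0), 1, 3), 2 / 3, tolerance = 1e-12)
  # exactly collinear samples cost nothing, anywhere in the signal
  y <- 2 * (1:20) + 1
  expect_equal(linear_segment_cost(y, 5, 17), 0, tolerance = 1e-12)
  # a line interpolates any two points
  expect_equal(linear_segment_cost(rnorm(10), 4, 5), 0, tolerance = 1e-10)
  expect_error(linear_segment_cost(1:10, 3, 3), "at least 2")
  # constant-mean variant is the centered sum of squares
  expect_equal(linear_segment_cost(c(1, 2, 6), 1, 3, cost = "constant"),
               sum((c(1, 2, 6) - 3)^2))
})

test_that("segment cost is subadditive under splitting", {
  set.seed(101)
  for (rep in 1:50) {
    y <- random_signal(sample(10:25, 1))
    n <- length(y)
    a <- sample(seq_len(n - 5), 1)
    b <- a + sample(4:min(8, n - a), 1)
    whole <- linear_segment_cost(y, a, b)
    for (s in (a + 1):(b - 2)) {
      expect_gte(whole + 1e-10,
                 linear_segment_cost(y, a, s) + linear_segment_cost(y, s + 1, b))
    }
  }
})

test_that("PELT finds no changepoints in a constant signal and recovers a clean slope change", {
  cfg <- penalty_config(beta = 1, min_len = 3)
  expect_equal(pelt_segment(rep(5, 20), cfg)$interior_count, 0L)
  # a discontinuous slope change (jump + new slope at sample 11) has a
  # unique zero-cost split; continuous kinks tie between the two positions
  # adjacent to the vertex, which lies on both lines
  y <- c(1:10, 100 + 3 * (11:20))
  res <- pelt_segment(y, cfg)
  expect_equal(res$interior, 10L)
  expect_equal(res$total_cost, cfg$beta, tolerance = 1e-10)  # one changepoint, zero RSS
  # sentinels frame the positions vector
  expect_equal(res$positions[1], 0L)
  expect_equal(res$positions[length(res$positions)], 20L)
})

test_that("PELT matches the exhaustive oracle on random short signals", {
  set.seed(202)
  for (i in 1:60) {
    y <- random_signal(sample(8:20, 1))
    cfg <- penalty_config(beta = runif(1, 0.1, 8), min_len = 3)
    p <- pelt_segment(y, cfg)
    e <- exhaustive_segment(y, cfg)
    expect_equal(p$total_cost, e$total_cost, tolerance = 1e-10)
  }
})

test_that("the number of changepoints is non-increasing in the penalty", {
  set.seed(303)
  y <- rep(c(0, 6, -3, 4), each = 12) + rnorm(48)
  betas <- c(0.5, 2, 8, 32, 128, 1e6)
  m <- vapply(betas, function(b)
    pelt_segment(y, penalty_config(beta = b, min_len = 3))$interior_count,
    integer(1))
  expect_true(all(diff(m) <= 0))
  expect_equal(m[length(m)], 0L)  # penalty dominates any cost saving
})

test_that("exhaustive search guards its input size and honors a dominating penalty", {
  expect_error(exhaustive_segment(rnorm(30), penalty_config(1)), "guard")
  y <- c(rep(0, 3), rep(5, 3))
  small <- exhaustive_segment(y, penalty_config(beta = 0.1, min_len = 3))
  expect_equal(small$interior, 3L)
  huge <- exhaustive_segment(y, penalty_config(beta = 1e9, min_len = 3))
  expect_equal(huge$interior_count, 0L)
  flat <- exhaustive_segment(rep(2, 5), penalty_config(beta = 1, min_len = 3))
  expect_equal(flat$interior_count, 0L)
  expect_equal(flat$total_cost, 0, tolerance = 1e-12)
})

test_that("default penalty follows the robust-noise BIC recipe", {
  set.seed(404)
  y <- rnorm(100)
  cfg <- default_penalty(y)
  sigma <- mad(diff(y)) / sqrt(2)
  expect_equal(cfg$sigma_hat, sigma, tolerance = 1e-12)
  expect_equal(cfg$beta, 2 * sigma^2 * log(100), tolerance = 1e-12)
  expect_equal(cfg$min_len, 3L)
  # scale equivariance: beta scales with the square of the signal scale
  cfg7 <- default_penalty(7 * y)
  expect_equal(cfg7$beta, 49 * cfg$beta, tolerance = 1e-9)
  # a noise-free ramp has no scale to estimate
  expect_warning(default_penalty(as.numeric(1:50)), "degenerate")
})

test_that("auto-penalized positions are stable under rescaling of the signal", {
  set.seed(505)
  y <- rep(c(0, 8, 3), each = 15) + rnorm(45)
  a <- pelt_segment(y, default_penalty(y))
  b <- pelt_segment(100 * y, default_penalty(100 * y))
  expect_equal(a$positions, b$positions)
})
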