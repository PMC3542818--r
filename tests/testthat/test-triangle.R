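test_that("MUE boundaries match closed forms and conventions", {
  # symmetric case: the two incomplete-beta relations mirror, p_hat = 1/2
  for (M in c(1, 2.5, 7, 40)) {
    est <- mue_success_prob(M / 2, M)
    expect_equal(est$p_hat, 0.5, tolerance = 1e-10)
    expect_equal(est$odds, 1, tolerance = 1e-9)
  }

  # I_x(2,2) = 3x^2 - 2x^3 = 1/2 at x = 1/2; I_x(1,3) = 1 - (1-x)^3
  est <- mue_success_prob(1, 3)
  expect_equal(est$p_hat1, 0.5, tolerance = 1e-10)
  expect_equal(est$p_hat2, 1 - 2^(-1 / 3), tolerance = 1e-10)
  expect_equal(est$p_hat, (0.5 + 1 - 2^(-1 / 3)) / 2, tolerance = 1e-10)

  # zero successes: lower boundary pinned at 0, upper from I_x(1,4)
  est0 <- mue_success_prob(0, 4)
  expect_equal(est0$p_hat2, 0)
  expect_equal(est0$p_hat1, 1 - 2^(-1 / 4), tolerance = 1e-10)
  expect_equal(est0$p_hat, (1 - 2^(-1 / 4)) / 2, tolerance = 1e-10)

  # all successes: upper boundary pinned at 1
  est1 <- mue_success_prob(3, 3)
  expect_equal(est1$p_hat1, 1)
  expect_equal(est1$p_hat2, 2^(-1 / 3), tolerance = 1e-10)

  expect_error(mue_success_prob(1, 0), "positive")
  expect_error(mue_success_prob(-1, 3), "\\[0, M\\]")
  expect_error(mue_success_prob(4, 3), "\\[0, M\\]")
})

test_that("MUE satisfies the binomial tail conditions at integer counts", {
  # spot-check here; the exhaustive M <= 50 sweep lives in the acceptance suite
  for (case in list(c(2, 9), c(5, 12), c(0, 7), c(17, 17), c(1, 30))) {
    m <- case[1]; M <- case[2]
    est <- mue_success_prob(m, M)
    orc <- mue_oracle(m, M)
    expect_equal(est$p_hat1, orc$p_hat1, tolerance = 1e-8)
    expect_equal(est$p_hat2, orc$p_hat2, tolerance = 1e-8)
    if (m < M) expect_equal(binom_lower_tail(m, M, est$p_hat1), 0.5,
                            tolerance = 1e-8)
    if (m > 0) expect_equal(binom_upper_tail(m, M, est$p_hat2), 0.5,
                            tolerance = 1e-8)
  }
})

test_that("MUE is monotone and converges to the MLE at large counts", {
  M <- 20
  p_hats <- vapply(seq(0, M, by = 0.5),
                   function(m) mue_success_prob(m, M)$p_hat, numeric(1))
  expect_true(all(diff(p_hats) > 0))

  for (frac in c(0.2, 0.5, 0.8)) {
    mle_odds <- frac / (1 - frac)
    err <- vapply(c(10, 100, 1000, 10000), function(lambda) {
      abs(mue_success_prob(frac * lambda, lambda)$odds - mle_odds)
    }, numeric(1))
    expect_true(all(diff(err) <= 1e-12))   # already ~0 for symmetric counts
    expect_lt(err[4], 1e-3)
  }
})

test_that("triangle statistic normalizes against the uniform null", {
  # uniform landscape at high mass: MUE -> MLE = B/A = null odds, t -> 1
  u <- 1e3
  t_unif <- triangle_statistic(75 * u, 50 * u, 75 * u)
  expect_gt(t_unif, 0.98)
  expect_lt(t_unif, 1.02)

  # symmetric in the flanks
  expect_equal(triangle_statistic(3, 10, 7), triangle_statistic(7, 10, 3))

  # strictly increasing in the central mass at fixed flanks
  ts <- vapply(seq(0, 30, by = 3),
               function(B) triangle_statistic(10, B, 10), numeric(1))
  expect_true(all(diff(ts) > 0))

  # empty central window: frozen from the closed form
  # p_hat1 = 1 - 2^(-1/10), p_hat2 = 0 => t = 0.0519652
  expect_equal(triangle_statistic(10, 0, 10), 0.05196523, tolerance = 1e-7)

  # empty window convention
  expect_equal(triangle_statistic(0, 0, 0), 0)
  expect_error(triangle_statistic(-1, 2, 3), "non-negative")
})

test_that("scan_triangle matches the naive per-window oracle exactly", {
  set.seed(301)
  scores <- stats::rpois(2000, 0.3) * stats::runif(2000)
  land <- structure(list(chrom = "chr", start = 1L, scores = scores),
                    class = "landscape")
  track <- scan_triangle(land)
  expect_length(track$t_values, 2000 - 200 + 1)
  expect_identical(track$t_values, scan_triangle_oracle(scores))
  expect_true(all(is.finite(track$t_values)) && all(track$t_values >= 0))
})

test_that("scan_triangle degenerate inputs behave as documented", {
  zeros <- structure(list(chrom = "chr", start = 1L, scores = numeric(400)),
                     class = "landscape")
  expect_true(all(scan_triangle(zeros)$t_values == 0))

  unif <- structure(list(chrom = "chr", start = 1L,
                         scores = rep(2, 600)), class = "landscape")
  tv <- scan_triangle(unif)$t_values
  expect_equal(length(unique(tv)), 1L)  # translation invariance

  short <- structure(list(chrom = "chr", start = 1L, scores = numeric(50)),
                     class = "landscape")
  expect_warning(tr <- scan_triangle(short), "shorter")
  expect_length(tr$t_values, 0L)
})

test_that("a single read cluster puts the t-plateau around its center", {
  pmf <- beta_offset_pmf()
  c0 <- 500L
  scores <- numeric(1000)
  scores[(c0 - 5):(c0 + 5)] <- unclass(pmf)[1:11]
  land <- structure(list(chrom = "chr", start = 1L, scores = scores),
                    class = "landscape")
  tv <- scan_triangle(land)$t_values
  top <- which(tv == max(tv))
  # all max-t windows have A = C = 0 (mass fully central); their centers
  # bracket the true center symmetrically even though argmax is the leftmost
  centers <- top + 100L
  expect_true(min(centers) <= c0 && max(centers) >= c0)
  expect_lt(abs(mean(range(centers)) - c0), 2)
})
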