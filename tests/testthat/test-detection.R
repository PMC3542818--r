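triangle_track <- function(t, chrom = "chr", start = 1L) {
  structure(list(chrom = chrom, start_offset = start, t_values = t),
            class = "triangle_track")
}

test_that("N-statistic fires on isolated strict maxima only", {
  t <- rep(0.1, 300)
  t[150] <- 2.0
  n <- n_statistic(triangle_track(t))$n_values
  expect_equal(which(n == 1L), 150L)

  # equal adjacent maxima: strict left product forces leftmost-wins
  t2 <- rep(0.1, 300)
  t2[150:151] <- 2.0
  n2 <- n_statistic(triangle_track(t2))$n_values
  expect_equal(which(n2 == 1L), 150L)

  # nothing reaches the cutoff
  expect_true(all(n_statistic(triangle_track(rep(1.69, 300)))$n_values == 0L))

  # peaks near the track edges stay callable (out-of-range terms neutral)
  t3 <- rep(0.1, 40)
  t3[3] <- 2.0
  expect_equal(which(n_statistic(triangle_track(t3))$n_values == 1L), 3L)
})

test_that("insurance sums veto peaks with a similar clump one offset away", {
  t <- rep(0.1, 400)
  t[200] <- 2.0
  # ten windows of 1.5 at offsets +69..+78: sum 15 > 10 => veto
  t[200 + 69:78] <- 1.5
  n <- n_statistic(triangle_track(t))$n_values
  expect_equal(n[200], 0L)
  expect_identical(n, nstat_oracle(t))

  # same clump on the left side
  t4 <- rep(0.1, 400)
  t4[200] <- 2.0
  t4[200 - 77:68] <- 1.5
  expect_equal(n_statistic(triangle_track(t4))$n_values[200], 0L)

  # clump below the threshold total does not veto
  t5 <- rep(0.1, 400)
  t5[200] <- 2.0
  t5[200 + 69:78] <- 0.9
  expect_equal(n_statistic(triangle_track(t5))$n_values[200], 1L)
})

test_that("N-statistic equals the literal indicator-product oracle", {
  set.seed(77)
  for (rep in 1:60) {
    kind <- rep %% 3
    t <- if (kind == 0) {
      stats::runif(150, 0, 3)
    } else if (kind == 1) {
      # sparse spikes over near-zero background, with plateaus
      v <- stats::runif(150, 0, 0.2)
      at <- sample(150, 6)
      v[at] <- sample(c(1.5, 2, 2, 4.5), 6, replace = TRUE)
      v[pmin(at + 1, 150)] <- v[at]   # adjacent ties
      v
    } else {
      # smooth correlated track
      abs(stats::filter(stats::rnorm(170, 1.5, 1), rep(1 / 21, 21),
                        sides = 2))[11:160]
    }
    t[is.na(t)] <- 0
    expect_identical(n_statistic(triangle_track(t))$n_values, nstat_oracle(t))
  }
})

test_that("calls are decorrelated: hits at least 26 positions apart", {
  # two hits closer than 26 are impossible: the later one's strict left
  # product and the earlier one's non-strict right product would contradict
  set.seed(78)
  any_multi <- FALSE
  for (rep in 1:40) {
    v <- stats::runif(200, 0, 0.3)
    at <- sample(200, 10)
    v[at] <- stats::runif(10, 1.7, 5)
    hits <- which(n_statistic(triangle_track(v))$n_values == 1L)
    if (length(hits) >= 2) {
      any_multi <- TRUE
      expect_true(all(diff(hits) >= 26))
    }
  }
  expect_true(any_multi)   # the property was actually exercised
})

test_that("candidates sit at window centers with the window's statistic", {
  t <- rep(0.1, 1200)
  t[901] <- 2.5
  t[961] <- 3.5
  track <- triangle_track(t)
  cand <- candidates(track, n_statistic(track))
  expect_equal(cand$center, c(1001L, 1061L))
  expect_equal(cand$t_stat, c(2.5, 3.5))
  expect_true(all(is.na(cand$fdr)))

  quiet <- triangle_track(rep(0.2, 300))
  expect_equal(nrow(candidates(quiet, n_statistic(quiet))), 0L)
})

test_that("chunk plans tile chromosomes with adequate flanks", {
  g <- genome_table(c(chrA = 10000, chrB = 3000))
  plan <- plan_chunks(g, target_interval = 5000)
  a <- plan[plan$chrom == "chrA", ]
  expect_equal(nrow(a), 2L)
  expect_equal(a$core_start, c(1, 5001))
  expect_equal(a$core_end, c(5000, 10000))
  # flanks of W + 103 where in-bounds
  expect_equal(a$start, c(1, 5001 - 303))
  expect_equal(a$end, c(5000 + 303, 10000))
  b <- plan[plan$chrom == "chrB", ]
  expect_equal(nrow(b), 1L)
  expect_equal(c(b$core_start, b$core_end), c(1, 3000))

  expect_error(plan_chunks(g, target_interval = 100), "10 \\* W")

  # cores tile every chromosome exactly
  set.seed(5)
  g2 <- genome_table(c(c1 = 123457, c2 = 7919))
  p2 <- plan_chunks(g2, target_interval = 20000)
  for (chrom in names(g2)) {
    rows <- p2[p2$chrom == chrom, ]
    expect_equal(rows$core_start[1], 1)
    expect_equal(rows$core_end[nrow(rows)], unname(unclass(g2)[chrom]))
    if (nrow(rows) > 1) {
      expect_equal(rows$core_start[-1], rows$core_end[-nrow(rows)] + 1)
    }
  }
})

test_that("chunked detection is bit-identical to a whole-chromosome scan", {
  sim <- planted_sim(seed = 19L)
  whole <- detect_candidates(sim$reads, sim$genome, target_interval = 1e6)
  chunked <- detect_candidates(sim$reads, sim$genome, target_interval = 4000)
  expect_identical(whole$center, chunked$center)
  expect_identical(whole$t_stat, chunked$t_stat)
  expect_true(all(diff(whole$center) >= 26))

  if (.Platform$OS.type == "unix") {
    par4 <- detect_candidates(sim$reads, sim$genome, target_interval = 4000,
                              threads = 4L)
    expect_identical(chunked, par4)
  }
})
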