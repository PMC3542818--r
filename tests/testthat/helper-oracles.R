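# Independent brute-force oracles used across the suite. These deliberately
# re-derive quantities from first principles (binomial sums, naive per-window
# summation, literal products of indicators) rather than calling the package's
# own fast paths.

# binomial lower/upper tail at integer (m, M): the exact conditions whose
# saturation defines the median-unbiased boundaries
binom_lower_tail <- function(m, M, p) sum(stats::dbinom(0:m, M, p))
binom_upper_tail <- function(m, M, p) sum(stats::dbinom(m:M, M, p))

# root-find the MUE boundaries from the binomial sums directly
mue_oracle <- function(m, M) {
  p1 <- if (m >= M) 1 else {
    stats::uniroot(function(p) binom_lower_tail(m, M, p) - 0.5,
                   c(0, 1), tol = 1e-12)$root
  }
  p2 <- if (m <= 0) 0 else {
    stats::uniroot(function(p) binom_upper_tail(m, M, p) - 0.5,
                   c(0, 1), tol = 1e-12)$root
  }
  list(p_hat1 = p1, p_hat2 = p2, p_hat = (p1 + p2) / 2)
}

# naive per-window triangle scan: double-precision left-to-right accumulation
# per window, one window at a time
scan_triangle_oracle <- function(scores, partition = window_partition()) {
  W <- partition$W
  n <- length(scores) - W + 1L
  acc <- function(from, w) {
    s <- 0
    for (k in from:(from + w - 1L)) s <- s + scores[k]
    s
  }
  vapply(seq_len(n), function(i) {
    A <- acc(i, partition$A_w)
    B <- acc(i + partition$A_w, partition$B_w)
    C <- acc(i + partition$A_w + partition$B_w, partition$C_w)
    triangle_statistic(A, B, C, partition)
  }, numeric(1))
}

# literal evaluation of the decorrelation statistic: products of indicators
# with out-of-range terms treated as t = 0
nstat_oracle <- function(t, t_c = 1.7) {
  n <- length(t)
  at <- function(j) if (j >= 1L && j <= n) t[j] else 0
  out <- integer(n)
  for (i in seq_len(n)) {
    if (t[i] < t_c) next
    ok <- TRUE
    for (j in (i - 25L):(i - 1L)) if (at(j) >= t[i]) { ok <- FALSE; break }
    if (ok) for (j in (i + 1L):(i + 26L)) {
      if (t[i] < at(j)) { ok <- FALSE; break }
    }
    if (ok) {
      s <- 0
      for (j in 1:10) s <- s + at(i + 68L + j)
      ok <- s <= 10
    }
    if (ok) {
      s <- 0
      for (j in 1:10) s <- s + at(i - 78L + j)
      ok <- s <= 10
    }
    out[i] <- as.integer(ok)
  }
  out
}

# landscape by direct per-read summation
landscape_oracle <- function(reads, chrom_length, pmf = beta_offset_pmf()) {
  scores <- numeric(chrom_length)
  for (r in seq_len(nrow(reads))) {
    for (j in 1:11) {
      x <- 67L + j
      k <- if (reads$strand[r] == "+") reads$pos5[r] + x else reads$pos5[r] - x
      if (k >= 1L && k <= chrom_length) scores[k] <- scores[k] + pmf[[j]]
    }
  }
  scores
}

# standard planted-nucleosome world used by several tests (the acceptance
# configuration: 20 nucleosomes on 50 kb, 50 reads/side, jitter sd 5)
planted_sim <- function(seed = 7L) {
  simulate_reads(sim_spec(50000L, seq(2000L, 40000L, by = 2000L),
                          reads_per_side = 50L, jitter_sd = 5,
                          background_rate = 1e-4, seed = seed))
}

read_sets_equal <- function(a, b) {
  identical(a$chrom, b$chrom) && identical(a$pos5, b$pos5) &&
    identical(a$strand, b$strand)
}
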