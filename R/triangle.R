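#' Scan-window partition
#'
#' A scan window of width W is split into three disjoint sub-windows A | B | C.
#' The central sub-window B (default 50 bp, about two superhelical turns of
#' ambiguity either side of the dyad) is where a positioned nucleosome
#' concentrates center probability mass; A and C are the flanks.
#'
#' @param W Scan-window width in bp (default 200).
#' @param A_w,B_w,C_w Sub-window widths; must satisfy `A_w + B_w + C_w = W`.
#' @return A `window_partition` list.
#' @export
window_partition <- function(W = 200L, A_w = 75L, B_w = 50L, C_w = 75L) {
  W <- as.integer(W); A_w <- as.integer(A_w)
  B_w <- as.integer(B_w); C_w <- as.integer(C_w)
  if (any(c(W, A_w, B_w, C_w) < 1L)) stop("window widths must be >= 1")
  if (A_w + B_w + C_w != W) stop("A_w + B_w + C_w must equal W")
  structure(list(W = W, A_w = A_w, B_w = B_w, C_w = C_w),
            class = "window_partition")
}

# null value of the odds B/A (and B/C) under a uniform landscape
null_odds <- function(partition) {
  2 * partition$B_w / (partition$W - partition$B_w)
}

ODDS_CAP <- 1e12  # finite stand-in for infinite odds when p_hat == 1

# moving_sum(s, w, offset, n)[i] = s[i+offset] + ... + s[i+offset+w-1],
# accumulated left-to-right in double precision. Ascending shifted-vector
# accumulation (not prefix sums) keeps the result bitwise independent of
# where the landscape slice starts, so chunked scans reproduce serial
# whole-chromosome scans exactly.
moving_sum <- function(s, w, offset, n) {
  i <- seq_len(n)
  out <- s[i + offset]
  for (d in seq_len(w - 1L)) out <- out + s[i + offset + d]
  out
}

#' Median-unbiased estimate of a Bernoulli success probability
#'
#' For m successes in M trials (both may be real-valued), the median-unbiased
#' estimate is the midpoint of the interval of p whose binomial tails at the
#' observed count are both at least 1/2. Its endpoints solve, in terms of the
#' regularized incomplete beta function I,
#' `I_p1(m + 1, M - m) = 1/2` and `I_p2(m, M - m + 1) = 1/2`,
#' i.e. p1 and p2 are medians of the corresponding beta distributions.
#' Boundary conventions: `m = 0` gives `p2 = 0`; `m = M` gives `p1 = 1`
#' (the saturated tail condition holds for every p, so the informative
#' endpoint is the extreme one).
#'
#' @param m Number of successes (real, `0 <= m <= M`).
#' @param M Number of trials (real, `> 0`).
#' @return List with `p_hat1`, `p_hat2`, `p_hat` (midpoint), and `odds`
#'   (`p_hat / (1 - p_hat)`, capped at 1e12).
#' @examples
#' mue_success_prob(1, 3)  # p_hat1 = 0.5, p_hat2 = 1 - 2^(-1/3)
#' @export
mue_success_prob <- function(m, M) {
  if (!is.finite(m) || !is.finite(M) || M <= 0) {
    stop("M must be positive and finite")
  }
  if (m < 0 || m > M) stop("m must lie in [0, M]")
  p1 <- if (m >= M) 1 else stats::qbeta(0.5, m + 1, M - m)
  p2 <- if (m <= 0) 0 else stats::qbeta(0.5, m, M - m + 1)
  p <- (p1 + p2) / 2
  odds <- if (p >= 1) ODDS_CAP else min(p / (1 - p), ODDS_CAP)
  list(p_hat1 = p1, p_hat2 = p2, p_hat = p, odds = odds)
}

# vectorized MUE odds for the scanner; m, M real vectors with 0 <= m <= M.
# M == 0 (empty numerator and denominator) hits both boundary conventions
# and returns odds 1; such windows are zeroed by the caller anyway.
mue_odds_vec <- function(m, M) {
  p1 <- rep(1, length(m))
  reg <- m < M
  if (any(reg)) p1[reg] <- stats::qbeta(0.5, m[reg] + 1, M[reg] - m[reg])
  p2 <- rep(0, length(m))
  pos <- m > 0
  if (any(pos)) p2[pos] <- stats::qbeta(0.5, m[pos], M[pos] - m[pos] + 1)
  p <- (p1 + p2) / 2
  ifelse(p >= 1, ODDS_CAP, pmin(p / (1 - p), ODDS_CAP))
}

#' Triangle statistic for one scan window
#'
#' Given the center-probability masses A, B, C in the three sub-windows, the
#' triangle statistic is the smaller of the two median-unbiased odds of B
#' against each flank, normalized by the uniform-null odds
#' `2 * B_w / (W - B_w)` (50/75 with defaults). Values near 1 indicate a
#' uniform window; values well above 1 indicate mass concentrated centrally,
#' the signature of a positioned nucleosome. An all-zero window scores 0.
#'
#' @param A,B,C Non-negative probability masses in the left, central, and
#'   right sub-windows.
#' @param partition A `window_partition`.
#' @return The triangle statistic (non-negative scalar).
#' @export
triangle_statistic <- function(A, B, C, partition = window_partition()) {
  if (any(c(A, B, C) < 0)) stop("sub-window masses must be non-negative")
  if (A + B + C == 0) return(0)
  odds_BA <- mue_odds_vec(B, A + B)
  odds_BC <- mue_odds_vec(B, C + B)
  min(odds_BA, odds_BC) / null_odds(partition)
}

#' Triangle statistics across a landscape
#'
#' Slides the W-bp scan window base-by-base across the landscape (successive
#' windows overlap by W - 1 bp) and computes the triangle statistic for every
#' window start. Sub-window masses come from prefix sums, and the
#' median-unbiased odds are computed vectorized, so the scan is linear time.
#'
#' @param landscape A `landscape`.
#' @param partition A `window_partition`.
#' @return A `triangle_track`: list with `chrom`, `start_offset` (genomic
#'   coordinate of the first window start), and numeric `t_values`.
#' @export
scan_triangle <- function(landscape, partition = window_partition()) {
  stopifnot(inherits(landscape, "landscape"))
  W <- partition$W
  s <- landscape$scores
  L <- length(s)
  if (L < W) {
    warning("interval shorter than the scan window (", L, " < ", W,
            "); empty triangle track")
    return(structure(list(chrom = landscape$chrom,
                          start_offset = landscape$start,
                          t_values = numeric(0)),
                     class = "triangle_track"))
  }
  n <- L - W + 1L
  A <- moving_sum(s, partition$A_w, offset = 0L, n = n)
  B <- moving_sum(s, partition$B_w, offset = partition$A_w, n = n)
  C <- moving_sum(s, partition$C_w, offset = partition$A_w + partition$B_w,
                  n = n)
  tot <- A + B + C
  t_values <- numeric(n)
  nz <- tot > 0
  if (any(nz)) {
    odds_BA <- mue_odds_vec(B[nz], A[nz] + B[nz])
    odds_BC <- mue_odds_vec(B[nz], C[nz] + B[nz])
    t_values[nz] <- pmin(odds_BA, odds_BC) / null_odds(partition)
  }
  structure(list(chrom = landscape$chrom, start_offset = landscape$start,
                 t_values = t_values),
            class = "triangle_track")
}
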