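# Offset support of the read-to-center distance: a read's 5' end sits one
# MNase cut site away from the nucleosome edge, so the center lies ~146/2 = 73
# bp away, with 5 bp of cut ambiguity on either side.
OFFSET_MIN <- 68L
OFFSET_MAX <- 78L
OFFSET_SUPPORT <- OFFSET_MIN:OFFSET_MAX   # 11 bins
OFFSET_SPAN <- 11L

#' Discretized beta distribution of read-to-center offsets
#'
#' The distance X from a read's 5' end to its nucleosome center is modelled on
#' the integer support \{68, ..., 78\}; the probability of each 1-bp bin is the
#' integral of a beta(alpha, beta) density rescaled onto \[68, 79). Under the
#' change of variables u = (x - 68)/11, each bin probability is an exact
#' difference of regularized incomplete beta values, so the pmf sums to 1 to
#' machine precision.
#'
#' @param alpha,beta_param Beta shape parameters (> 0). Defaults are
#'   maximum-likelihood fits to published yeast paired-end half-distances.
#' @return An `offset_pmf`: numeric vector of 11 probabilities named by offset,
#'   with attributes `alpha` and `beta_param`.
#' @examples
#' p <- beta_offset_pmf(1, 1)    # uniform: each bin 1/11
#' sum(beta_offset_pmf())        # 1
#' @export
beta_offset_pmf <- function(alpha = 1.9204, beta_param = 1.8937) {
  if (!is.finite(alpha) || !is.finite(beta_param) ||
      alpha <= 0 || beta_param <= 0) {
    stop("beta shape parameters must be strictly positive")
  }
  edges <- (0:OFFSET_SPAN) / OFFSET_SPAN
  cdf <- stats::pbeta(edges, alpha, beta_param)
  probs <- diff(cdf)
  probs <- probs / sum(probs)   # guards rounding in the last bit
  structure(stats::setNames(probs, OFFSET_SUPPORT),
            alpha = alpha, beta_param = beta_param,
            class = "offset_pmf")
}

#' @export
print.offset_pmf <- function(x, ...) {
  cat(sprintf("offset_pmf over {%d..%d}, alpha=%.4f beta=%.4f\n",
              OFFSET_MIN, OFFSET_MAX,
              attr(x, "alpha"), attr(x, "beta_param")))
  print(unclass(x)[seq_along(x)])
  invisible(x)
}

#' Build the nucleosome-center probability landscape for one chromosome
#'
#' Each forward read at 5' end y spreads its unit mass over coordinates
#' y + 68 .. y + 78 according to the offset pmf; each reverse read at y spreads
#' it over y - 78 .. y - 68 (mirrored). Per-coordinate masses are summed over
#' reads. Contributions falling outside \[start, end\] (or outside the
#' chromosome) are dropped, but the read keeps its in-bounds bins.
#'
#' @param reads A `read_set`, all on one chromosome.
#' @param chrom_length Chromosome length in bp.
#' @param pmf An `offset_pmf` (default shapes if omitted).
#' @param start,end Optional genomic sub-interval over which to materialize
#'   the landscape (defaults: whole chromosome). Used by the chunked scanner.
#' @return A `landscape`: list with `chrom`, `start`, and numeric `scores`
#'   where `scores[k]` is the summed center probability at genomic coordinate
#'   `start + k - 1`.
#' @export
build_landscape <- function(reads, chrom_length, pmf = beta_offset_pmf(),
                            start = 1L, end = chrom_length) {
  stopifnot(inherits(reads, "read_set"))
  if (length(unique(reads$chrom)) > 1L) {
    stop("build_landscape expects reads on a single chromosome")
  }
  start <- max(1L, as.integer(start))
  end <- min(as.integer(chrom_length), as.integer(end))
  n <- end - start + 1L
  if (n < 1L) stop("empty landscape interval")
  scores <- numeric(n)
  if (nrow(reads) > 0L) {
    fwd <- reads$strand == "+"
    # center coordinate for bin x: y + x (forward), y - x (reverse)
    for (j in seq_len(OFFSET_SPAN)) {
      x <- OFFSET_SUPPORT[j]
      coord <- ifelse(fwd, reads$pos5 + x, reads$pos5 - x)
      idx <- coord - start + 1L
      ok <- idx >= 1L & idx <= n
      if (any(ok)) {
        tab <- tabulate_weighted(idx[ok], n)
        scores <- scores + pmf[[j]] * tab
      }
    }
  }
  structure(list(chrom = if (nrow(reads)) reads$chrom[1] else NA_character_,
                 start = start, scores = scores),
            class = "landscape")
}

# integer counts of idx values in 1..n (tabulate, kept as double)
tabulate_weighted <- function(idx, n) {
  as.numeric(tabulate(idx, nbins = n))
}

#' Fit beta shape parameters from read-to-center half-distances
#'
#' Given empirical half-distances t between paired read ends (each pair flanks
#' one nucleosome, so t estimates the read-to-center offset), solves the
#' maximum-likelihood equations for a beta distribution rescaled to \[68, 79):
#' mean(log((t - 68)/11)) = digamma(alpha) - digamma(alpha + beta) and
#' mean(log((79 - t)/11)) = digamma(beta) - digamma(alpha + beta).
#' Newton iteration with the analytic trigamma Jacobian, started at (2, 2).
#'
#' @param half_distances Numeric vector of half-distances in bp; values
#'   outside the open interval (68, 79) are discarded first.
#' @param max_iter Maximum Newton iterations.
#' @return Named numeric vector `c(alpha = ..., beta_param = ...)`, with
#'   attribute `residual` (max absolute residual of the two equations).
#' @export
fit_beta_shapes <- function(half_distances, max_iter = 100L) {
  t <- half_distances[is.finite(half_distances) &
                        half_distances > OFFSET_MIN &
                        half_distances < OFFSET_MIN + OFFSET_SPAN]
  if (length(t) < 10L) {
    stop("need at least 10 half-distances strictly inside (68, 79); got ",
         length(t))
  }
  u <- (t - OFFSET_MIN) / OFFSET_SPAN
  L1 <- mean(log(u))
  L2 <- mean(log1p(-u))
  th <- c(2, 2)
  resid <- function(th) {
    c(digamma(th[1]) - digamma(sum(th)) - L1,
      digamma(th[2]) - digamma(sum(th)) - L2)
  }
  r <- resid(th)
  for (it in seq_len(max_iter)) {
    if (max(abs(r)) < 1e-10) break
    ts <- trigamma(sum(th))
    J <- rbind(c(trigamma(th[1]) - ts, -ts),
               c(-ts, trigamma(th[2]) - ts))
    step <- solve(J, r)
    # damp steps that would leave the positive orthant
    lambda <- 1
    repeat {
      cand <- th - lambda * step
      if (all(cand > 1e-8)) break
      lambda <- lambda / 2
      if (lambda < 1e-8) stop("beta MLE solver left the parameter domain")
    }
    th <- th - lambda * step
    r <- resid(th)
  }
  if (max(abs(r)) >= 1e-8) {
    stop(sprintf(
      "beta MLE solver did not converge: residuals (%.3g, %.3g) after %d iterations",
      r[1], r[2], max_iter))
  }
  structure(c(alpha = th[1], beta_param = th[2]), residual = max(abs(r)))
}
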