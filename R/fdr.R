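SHAKE_HALF_RANGE <- 73L

#' Shake read positions to simulate delocalized nucleosomes
#'
#' Shifts every read's 5' end by an independent integer drawn uniformly from
#' \{-73, ..., 73\} (half a nucleosome width either way), destroying the
#' clustered read signature of positioned nucleosomes while preserving read
#' count, strand balance, and overall coverage. Shifted positions are clamped
#' into \[1, chromosome length\].
#'
#' @param reads A `read_set`.
#' @param genome A `genome_table` covering the reads.
#' @param seed Integer seed; identical seeds reproduce identical shakes.
#' @return A `read_set` of the same size.
#' @export
shake_reads <- function(reads, genome, seed) {
  stopifnot(inherits(reads, "read_set"), inherits(genome, "genome_table"))
  n <- nrow(reads)
  if (n == 0L) return(reads)
  set.seed(as.integer(seed))
  shift <- sample.int(2L * SHAKE_HALF_RANGE + 1L, n, replace = TRUE) -
    (SHAKE_HALF_RANGE + 1L)
  pos <- reads$pos5 + shift
  clen <- unclass(genome)[reads$chrom]
  pos <- pmin(pmax(pos, 1L), as.integer(clen))
  read_set(reads$chrom, pos, reads$strand)
}

# number of values in `pool` that are >= each element of `thresholds`;
# sorted + findInterval, O((n+m) log n)
count_exceedances <- function(pool, thresholds) {
  if (length(pool) == 0L) return(integer(length(thresholds)))
  srt <- sort(pool)
  length(pool) - findInterval(thresholds, srt, left.open = TRUE)
}

#' Monte Carlo FDR estimation by read shaking
#'
#' For each of S simulations, all read positions are shaken uniformly in
#' \{-73, ..., 73\} and the full detection pipeline (landscape, triangle scan,
#' N-statistic) is re-run on the shaken reads with the real-data
#' configuration. For the j-th real candidate with triangle statistic t_j, let
#' M_j be the number of real candidates with statistic >= t_j and m_kj the
#' number of simulated candidates with statistic >= t_j in simulation k; the
#' estimated FDR is the average exceedance ratio `mean_k(m_kj) / M_j`
#' (clamped to \[0, 1\] for reporting).
#'
#' @param real_candidates `candidate_set` from [detect_candidates()] on
#'   `reads`.
#' @param reads,genome,pmf,partition,t_c,threads,target_interval The inputs
#'   and configuration of that detection run.
#' @param S Number of simulations (>= 1).
#' @param seed Integer master seed; per-simulation seeds are derived from it
#'   deterministically, so results do not depend on the thread count.
#' @return An `fdr_table` data.frame with one row per candidate: `chrom`,
#'   `center`, `t_stat`, `M`, `mean_sim_exceed`, `fdr`; per-simulation
#'   candidate counts and triangle statistics in attributes `sim_counts` and
#'   `sim_t`.
#' @export
estimate_fdr <- function(real_candidates, reads, genome,
                         pmf = beta_offset_pmf(),
                         partition = window_partition(), t_c = 1.7,
                         S = 3L, seed = 1L, threads = 1L,
                         target_interval = 1e6) {
  if (S < 1L) stop("number of simulations S must be >= 1")
  stopifnot(inherits(real_candidates, "candidate_set"))
  tj <- real_candidates$t_stat
  M <- count_exceedances(tj, tj)
  exceed <- matrix(0, nrow = length(tj), ncol = S)
  sim_t <- vector("list", S)
  for (k in seq_len(S)) {
    shaken <- shake_reads(reads, genome, seed = derive_seed(seed, k))
    sim <- detect_candidates(shaken, genome, pmf, partition, t_c,
                             threads = threads,
                             target_interval = target_interval)
    sim_t[[k]] <- sim$t_stat
    if (length(tj)) exceed[, k] <- count_exceedances(sim$t_stat, tj)
  }
  fdr_raw <- if (length(tj)) rowMeans(exceed) / M else numeric(0)
  structure(
    data.frame(chrom = real_candidates$chrom,
               center = real_candidates$center,
               t_stat = tj, M = M,
               mean_sim_exceed = if (length(tj)) rowMeans(exceed)
                                 else numeric(0),
               fdr = pmin(fdr_raw, 1),
               stringsAsFactors = FALSE),
    sim_counts = lengths(sim_t), sim_t = sim_t, S = S,
    class = c("fdr_table", "data.frame")
  )
}

# deterministic per-simulation seed below 2^31
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 7919 + k * 104729) %% 2147483647)
}

#' Filter candidates by FDR cutoff
#'
#' Retains exactly the candidates whose estimated FDR is at most `F`, and
#' fills the `fdr` column of the result.
#'
#' @param cands A `candidate_set`.
#' @param fdr_table The matching `fdr_table` from [estimate_fdr()].
#' @param F FDR cutoff in \[0, 1\] (default 0.01).
#' @return The filtered `candidate_set` with `fdr` populated.
#' @export
filter_candidates <- function(cands, fdr_table, F = 0.01) {
  stopifnot(inherits(cands, "candidate_set"), inherits(fdr_table, "fdr_table"))
  if (nrow(cands) != nrow(fdr_table) ||
      (nrow(cands) && any(cands$center != fdr_table$center))) {
    stop("fdr_table does not cover the candidate set")
  }
  cands$fdr <- fdr_table$fdr
  out <- cands[cands$fdr <= F, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("candidate_set", "data.frame")
  out
}
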