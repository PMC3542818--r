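# Eq-6 neighborhood constants. The left product runs over the 25 windows
# before i (strict inequality), the right product over the 26 windows after i
# (non-strict), which forces leftmost-wins tie-breaking on plateaus. The two
# "insurance" sums look one offset-support width away (+69..+78 and -77..-68
# relative to i) and veto the call when a similar clump of high triangle
# statistics sits one nucleosome away.
NSTAT_LEFT <- 25L
NSTAT_RIGHT <- 26L
INSURANCE_LEN <- 10L
INSURANCE_RIGHT_FROM <- 69L   # t_{i+68+j}, j = 1..10
INSURANCE_LEFT_FROM <- -77L   # t_{i-78+j}, j = 1..10
INSURANCE_MAX <- 10
# how far an N decision reaches into neighboring triangle statistics
NSTAT_REACH <- 78L

#' Decorrelated N-statistic over a triangle track
#'
#' Triangle statistics of heavily overlapping scan windows are strongly
#' autocorrelated, so a positioned nucleosome produces a clump of high values.
#' The N-statistic picks at most one window per clump: `N_i = 1` iff `t_i`
#' strictly exceeds the 25 values to its left, is at least the 26 values to
#' its right, reaches the cutoff `t_c`, and the sums of the 10 triangle
#' statistics one offset-width away on each side (positions i+69..i+78 and
#' i-77..i-68) do not exceed 10 — insurance against calling overlapping or
#' delocalized nucleosomes. Positions outside the track are treated as t = 0,
#' so every indicator they enter is satisfied and peaks near chromosome ends
#' remain callable.
#'
#' @param track A `triangle_track`.
#' @param t_c Critical triangle-statistic cutoff (default 1.7).
#' @return An `nstat_track`: list with `chrom`, `start_offset`, and an integer
#'   0/1 vector `n_values` aligned with the triangle track.
#' @export
n_statistic <- function(track, t_c = 1.7) {
  stopifnot(inherits(track, "triangle_track"))
  t <- track$t_values
  n <- length(t)
  if (n == 0L) {
    return(structure(list(chrom = track$chrom,
                          start_offset = track$start_offset,
                          n_values = integer(0)),
                     class = "nstat_track"))
  }
  pad <- NSTAT_REACH
  tp <- c(numeric(pad), t, numeric(pad))
  idx <- pad + seq_len(n)   # position of t_i inside tp

  # max over the 25 left neighbors / 26 right neighbors by iterated pmax
  left_max <- numeric(n)
  for (d in seq_len(NSTAT_LEFT)) left_max <- pmax(left_max, tp[idx - d])
  right_max <- numeric(n)
  for (d in seq_len(NSTAT_RIGHT)) right_max <- pmax(right_max, tp[idx + d])

  # insurance sums over the 10 offsets starting at `from`, relative to i;
  # same offset-independent accumulation as moving_sum
  sum_at <- function(from) {
    out <- tp[idx + from]
    for (d in seq_len(INSURANCE_LEN - 1L)) out <- out + tp[idx + from + d]
    out
  }
  right_ins <- sum_at(INSURANCE_RIGHT_FROM)
  left_ins <- sum_at(INSURANCE_LEFT_FROM)

  ok <- (t > left_max) & (t >= right_max) & (t >= t_c) &
    (right_ins <= INSURANCE_MAX) & (left_ins <= INSURANCE_MAX)
  structure(list(chrom = track$chrom, start_offset = track$start_offset,
                 n_values = as.integer(ok)),
            class = "nstat_track")
}

#' Candidate nucleosomes from the N-statistic
#'
#' Each window start i with `N_i = 1` becomes a candidate nucleosome centered
#' at `i + floor(W / 2)` (the scan-window center; i + 100 with defaults) with
#' that window's triangle statistic. The FDR column is NA until
#' [estimate_fdr()] fills it.
#'
#' @param track A `triangle_track`.
#' @param nstat The aligned `nstat_track`.
#' @param partition The `window_partition` used for the scan.
#' @return A data.frame of class `candidate_set` with columns
#'   `chrom`, `center`, `t_stat`, `fdr`.
#' @export
candidates <- function(track, nstat, partition = window_partition()) {
  stopifnot(inherits(track, "triangle_track"), inherits(nstat, "nstat_track"))
  if (length(track$t_values) != length(nstat$n_values) ||
      track$start_offset != nstat$start_offset) {
    stop("triangle and N-statistic tracks are not aligned")
  }
  hit <- which(nstat$n_values == 1L)
  starts <- track$start_offset + hit - 1L
  candidate_set(
    chrom = rep(track$chrom, length(hit)),
    center = starts + partition$W %/% 2L,
    t_stat = track$t_values[hit],
    fdr = rep(NA_real_, length(hit))
  )
}

candidate_set <- function(chrom = character(), center = integer(),
                          t_stat = numeric(), fdr = numeric()) {
  structure(
    data.frame(chrom = as.character(chrom), center = as.integer(center),
               t_stat = as.numeric(t_stat), fdr = as.numeric(fdr),
               stringsAsFactors = FALSE),
    class = c("candidate_set", "data.frame")
  )
}

#' Chunked scanning plan for a genome
#'
#' Chromosomes are divided into core intervals that tile the chromosome
#' without gaps or overlaps; each core is padded on both sides by a flank of
#' `W + 103` bp (clipped at chromosome ends) so that every triangle statistic
#' and every N-statistic neighborhood term needed to decide calls inside the
#' core can be computed from the padded interval alone. Chunks are pure,
#' independent work units: processing them in any order, serially or in
#' parallel, reproduces the serial whole-chromosome result exactly.
#'
#' @param genome A `genome_table`.
#' @param partition A `window_partition`.
#' @param target_interval Approximate core length in bp (default 1e6; must be
#'   at least `10 * W`).
#' @return A `chunk_plan` data.frame with columns `chrom`, `start`, `end`,
#'   `core_start`, `core_end`.
#' @export
plan_chunks <- function(genome, partition = window_partition(),
                        target_interval = 1e6) {
  stopifnot(inherits(genome, "genome_table"))
  W <- partition$W
  if (target_interval < 10 * W) stop("target_interval must be >= 10 * W")
  flank <- W + NSTAT_LEFT + NSTAT_REACH   # = W + 103
  rows <- lapply(names(genome), function(chrom) {
    L <- unclass(genome)[[chrom]]
    k <- max(1L, ceiling(L / target_interval))
    bounds <- floor(seq(0, L, length.out = k + 1))
    core_start <- bounds[-length(bounds)] + 1
    core_end <- bounds[-1]
    data.frame(chrom = chrom,
               start = pmax(1, core_start - flank),
               end = pmin(L, core_end + flank),
               core_start = core_start, core_end = core_end,
               stringsAsFactors = FALSE)
  })
  structure(do.call(rbind, rows), class = c("chunk_plan", "data.frame"))
}

# Process one chunk: local landscape -> triangle -> N -> candidates whose
# window start falls in the core. `reads` must contain at least all reads
# within NSTAT_REACH + offset support of the interval; passing the whole
# chromosome is always correct.
scan_chunk <- function(reads, chrom, chrom_length, chunk, pmf, partition,
                       t_c) {
  sel <- reads$chrom == chrom &
    reads$pos5 >= chunk$start - (OFFSET_MAX + 1L) &
    reads$pos5 <= chunk$end + (OFFSET_MAX + 1L)
  sub <- reads[sel, , drop = FALSE]
  class(sub) <- c("read_set", "data.frame")
  if (nrow(sub) > 0L) sub$chrom <- rep(chrom, nrow(sub))
  land <- build_landscape(sub, chrom_length, pmf,
                          start = chunk$start, end = chunk$end)
  land$chrom <- chrom
  track <- suppressWarnings(scan_triangle(land, partition))
  if (length(track$t_values) == 0L) return(candidate_set())
  nst <- n_statistic(track, t_c)
  cand <- candidates(track, nst, partition)
  start_i <- cand$center - partition$W %/% 2L
  cand[start_i >= chunk$core_start & start_i <= chunk$core_end, ,
       drop = FALSE]
}

#' Detect candidate nucleosomes across a genome
#'
#' Runs landscape construction, the triangle scan, and the N-statistic over
#' every chromosome of the genome, chunked per [plan_chunks()] and optionally
#' spread over a worker pool. Workers are pure functions of their chunk, and
#' results are concatenated in plan order, so the output is identical for any
#' thread count.
#'
#' @param reads A `read_set` (any number of chromosomes).
#' @param genome A `genome_table`.
#' @param pmf An `offset_pmf`.
#' @param partition A `window_partition`.
#' @param t_c Triangle-statistic cutoff.
#' @param threads Worker-pool size (forked processes; 1 = serial).
#' @param target_interval Chunk core size in bp.
#' @return A `candidate_set` sorted by genome order, then center.
#' @export
detect_candidates <- function(reads, genome, pmf = beta_offset_pmf(),
                              partition = window_partition(), t_c = 1.7,
                              threads = 1L, target_interval = 1e6) {
  stopifnot(inherits(reads, "read_set"))
  plan <- plan_chunks(genome, partition, target_interval)
  lens <- unclass(genome)
  worker <- function(r) {
    chunk <- plan[r, ]
    scan_chunk(reads, chunk$chrom, lens[[chunk$chrom]], chunk, pmf,
               partition, t_c)
  }
  rows <- seq_len(nrow(plan))
  if (threads > 1L && .Platform$OS.type == "unix") {
    parts <- parallel::mclapply(rows, worker, mc.cores = threads,
                                mc.preschedule = TRUE)
    failed <- vapply(parts, inherits, logical(1), "try-error")
    if (any(failed)) stop("chunk worker failed: ", parts[[which(failed)[1]]])
  } else {
    parts <- lapply(rows, worker)
  }
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  class(out) <- c("candidate_set", "data.frame")
  out
}
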