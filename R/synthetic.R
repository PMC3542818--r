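#' Specification for a synthetic MNase-seq read set
#'
#' Describes a single synthetic chromosome carrying positioned nucleosomes at
#' known centers. Each positioned nucleosome contributes a cluster of
#' forward-strand 5' ends ~73 bp left of its center and reverse-strand 5' ends
#' ~73 bp right of it, with Gaussian positional jitter of the cut sites, over
#' a uniform strand-balanced background. Jitter is Gaussian-rounded rather
#' than beta-distributed so the generator stays independent of the detection
#' model it is used to test.
#'
#' @param chrom_length Chromosome length in bp.
#' @param centers True nucleosome center coordinates; each must be at least
#'   112 bp from both chromosome ends.
#' @param reads_per_side Reads per flank per nucleosome (>= 0).
#' @param jitter_sd Standard deviation of the Gaussian cut-site jitter in bp.
#' @param background_rate Background reads per bp (uniform positions, random
#'   strand).
#' @param seed Integer seed; the generator is deterministic given the spec.
#' @param chrom Chromosome name used in the output.
#' @return A `sim_spec` list.
#' @export
sim_spec <- function(chrom_length, centers, reads_per_side = 50L,
                     jitter_sd = 5, background_rate = 1e-4, seed = 1L,
                     chrom = "chrS") {
  chrom_length <- as.integer(chrom_length)
  centers <- as.integer(centers)
  if (any(centers < 112L) || any(centers > chrom_length - 112L)) {
    stop("true centers must be at least 112 bp from chromosome ends")
  }
  if (reads_per_side < 0L || background_rate < 0 || jitter_sd < 0) {
    stop("reads_per_side, jitter_sd and background_rate must be non-negative")
  }
  structure(list(chrom_length = chrom_length, centers = centers,
                 reads_per_side = as.integer(reads_per_side),
                 jitter_sd = jitter_sd, background_rate = background_rate,
                 seed = as.integer(seed), chrom = chrom),
            class = "sim_spec")
}

#' Simulate single-end MNase-seq reads with known ground truth
#'
#' For each true center c, places `reads_per_side` forward reads at
#' `c - 73 + round(N(0, jitter_sd))` and as many reverse reads at
#' `c + 73 + round(N(0, jitter_sd))`, then adds Poisson
#' (`chrom_length * background_rate`) background reads uniform in position
#' and strand. Positions are clamped into the chromosome.
#'
#' @param spec A `sim_spec`.
#' @return List with `reads` (a `read_set`), `truth` (data.frame of true
#'   centers), and `genome` (a one-chromosome `genome_table`).
#' @export
simulate_reads <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  set.seed(spec$seed)
  L <- spec$chrom_length
  pos <- integer(0)
  strand <- character(0)
  origin <- character(0)
  for (c0 in spec$centers) {
    nps <- spec$reads_per_side
    if (nps > 0L) {
      jf <- as.integer(round(stats::rnorm(nps, 0, spec$jitter_sd)))
      jr <- as.integer(round(stats::rnorm(nps, 0, spec$jitter_sd)))
      pos <- c(pos, c0 - 73L + jf, c0 + 73L + jr)
      strand <- c(strand, rep("+", nps), rep("-", nps))
      origin <- c(origin, rep("nucleosome", 2L * nps))
    }
  }
  nbg <- stats::rpois(1, L * spec$background_rate)
  if (nbg > 0L) {
    pos <- c(pos, sample.int(L, nbg, replace = TRUE))
    strand <- c(strand, sample(c("+", "-"), nbg, replace = TRUE))
    origin <- c(origin, rep("background", nbg))
  }
  pos <- pmin(pmax(pos, 1L), L)
  genome <- genome_table(stats::setNames(L, spec$chrom))
  list(
    reads = read_set(rep(spec$chrom, length(pos)), pos, strand, genome),
    truth = data.frame(chrom = rep(spec$chrom, length(spec$centers)),
                       center = spec$centers, stringsAsFactors = FALSE),
    genome = genome
  )
}

#' Write simulated reads as a BED6 or SAM fixture
#'
#' Encodes each read as a 50-bp alignment so that re-reading the file through
#' [read_alignments()] recovers exactly the same (chrom, 5' end, strand)
#' triples: a forward read at p becomes an alignment spanning
#' \[p, p + 49\], a reverse read at p one spanning \[p - 49, p\].
#'
#' @param reads A `read_set`.
#' @param genome A `genome_table` (required for the SAM header and bounds).
#' @param format `"bed"` or `"sam"`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fixture <- function(reads, genome, format = c("bed", "sam"), path) {
  format <- match.arg(format)
  stopifnot(inherits(reads, "read_set"), inherits(genome, "genome_table"))
  read_len <- 50L
  fwd <- reads$strand == "+"
  left <- ifelse(fwd, reads$pos5, reads$pos5 - read_len + 1L)
  right <- left + read_len - 1L
  clen <- unclass(genome)[reads$chrom]
  if (nrow(reads) && (any(left < 1L) || any(right > clen))) {
    stop("cannot encode reads whose 50-bp alignment leaves the chromosome")
  }
  con <- file(path, "w")
  on.exit(close(con))
  if (format == "bed") {
    if (nrow(reads)) {
      writeLines(sprintf("%s\t%d\t%d\tread%d\t0\t%s", reads$chrom,
                         left - 1L, right, seq_len(nrow(reads)),
                         reads$strand), con)
    }
  } else {
    writeLines("@HD\tVN:1.6\tSO:unknown", con)
    writeLines(sprintf("@SQ\tSN:%s\tLN:%d", names(genome),
                       as.integer(unclass(genome))), con)
    if (nrow(reads)) {
      flag <- ifelse(fwd, 0L, 16L)
      writeLines(sprintf("read%d\t%d\t%s\t%d\t60\t%dM\t*\t0\t0\t*\t*",
                         seq_len(nrow(reads)), flag, reads$chrom, left,
                         read_len), con)
    }
  }
  invisible(path)
}
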