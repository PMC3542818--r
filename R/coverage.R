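#' Nucleosome coverage track
#'
#' Builds the display coverage used alongside candidate centers: each
#' positive-strand read is extended 75 bases to the right of its 5' end
#' (footprint \[p, p + 74\]) and then shifted 37 bases right, so it increments
#' counts on \[p + 37, p + 111\]; each negative-strand read is extended 75
#' bases left and shifted 37 left, incrementing \[p - 111, p - 37\]. The two
#' half-tracks pile up near nucleosome centers. Out-of-bounds positions are
#' dropped.
#'
#' @param reads A `read_set` on one chromosome.
#' @param chrom_length Chromosome length in bp.
#' @return A `coverage_track`: list with `chrom` and integer `counts` of
#'   length `chrom_length`.
#' @export
coverage_track <- function(reads, chrom_length) {
  stopifnot(inherits(reads, "read_set"))
  if (length(unique(reads$chrom)) > 1L) {
    stop("coverage_track expects reads on a single chromosome")
  }
  L <- as.integer(chrom_length)
  counts <- integer(L)
  if (nrow(reads) > 0L) {
    fwd <- reads$strand == "+"
    lo <- ifelse(fwd, reads$pos5 + 37L, reads$pos5 - 111L)
    hi <- lo + 74L
    lo <- pmax(lo, 1L)
    hi <- pmin(hi, L)
    ok <- lo <= hi
    # difference array: +1 at lo, -1 after hi, then cumulative sum
    d <- integer(L + 1L)
    tlo <- tabulate(lo[ok], nbins = L)
    thi <- tabulate(hi[ok] + 1L, nbins = L + 1L)
    d[seq_len(L)] <- tlo
    d <- d - thi
    counts <- cumsum(d[seq_len(L)])
  }
  structure(list(chrom = if (nrow(reads)) reads$chrom[1] else NA_character_,
                 counts = as.integer(counts)),
            class = "coverage_track")
}

#' Per-strand histograms of read 5'-end positions
#'
#' @param reads A `read_set` on one chromosome.
#' @param from,to 1-based inclusive coordinate range (`from <= to`).
#' @return List with integer vectors `forward` and `reverse`, one count per
#'   position in `from:to`.
#' @export
strand_histograms <- function(reads, from, to) {
  stopifnot(inherits(reads, "read_set"))
  from <- as.integer(from); to <- as.integer(to)
  if (from > to) stop("from must be <= to")
  n <- to - from + 1L
  hist_of <- function(strand) {
    p <- reads$pos5[reads$strand == strand]
    p <- p[p >= from & p <= to]
    tabulate(p - from + 1L, nbins = n)
  }
  list(forward = hist_of("+"), reverse = hist_of("-"))
}

#' Write a coverage track as BedGraph
#'
#' Standard 0-based half-open BedGraph with runs of equal coverage collapsed
#' into single records; zero-coverage runs are omitted.
#'
#' @param track A `coverage_track`.
#' @param out_path Output file path.
#' @return `out_path`, invisibly.
#' @export
write_bedgraph <- function(track, out_path) {
  stopifnot(inherits(track, "coverage_track"))
  counts <- track$counts
  r <- rle(counts)
  end1 <- cumsum(r$lengths)          # 1-based inclusive run ends
  start0 <- end1 - r$lengths         # 0-based run starts
  keep <- r$values != 0L
  con <- file(out_path, "w")
  on.exit(close(con))
  writeLines(sprintf("track type=bedGraph name=%s_coverage", track$chrom),
             con)
  if (any(keep)) {
    writeLines(sprintf("%s\t%d\t%d\t%d", track$chrom, start0[keep],
                       end1[keep], r$values[keep]), con)
  }
  invisible(out_path)
}
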