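# order candidates by genome-table chromosome order, then center
order_candidates <- function(cands, genome) {
  ord <- order(match(cands$chrom, names(genome)), cands$center)
  out <- cands[ord, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("candidate_set", "data.frame")
  out
}

#' Write candidate nucleosome centers as a TXT table
#'
#' Tab-separated columns `chrom`, `center`, `t_stat`, `fdr`, one row per
#' candidate, preceded by a header line. FDRs are clamped to \[0, 1\].
#'
#' @param cands A `candidate_set`, sorted by (chrom, center).
#' @param out_path Output file path.
#' @return `out_path`, invisibly.
#' @export
write_centers_txt <- function(cands, out_path) {
  stopifnot(inherits(cands, "candidate_set"))
  con <- file(out_path, "w")
  on.exit(close(con))
  writeLines("chrom\tcenter\tt_stat\tfdr", con)
  if (nrow(cands)) {
    fdr <- pmin(pmax(cands$fdr, 0), 1)
    writeLines(sprintf("%s\t%d\t%.6g\t%.6g", cands$chrom, cands$center,
                       cands$t_stat, fdr), con)
  }
  invisible(out_path)
}

#' Write candidate centers and triangle statistics as a WIG track
#'
#' variableStep WIG with span 1: one declaration block per chromosome that has
#' candidates, with the triangle statistic as the value at each center
#' position. Loadable in standard genome browsers.
#'
#' @inheritParams write_centers_txt
#' @return `out_path`, invisibly.
#' @export
write_wig <- function(cands, out_path) {
  stopifnot(inherits(cands, "candidate_set"))
  con <- file(out_path, "w")
  on.exit(close(con))
  writeLines("track type=wiggle_0 name=nucleosome_centers", con)
  for (chrom in unique(cands$chrom)) {
    rows <- cands[cands$chrom == chrom, , drop = FALSE]
    writeLines(sprintf("variableStep chrom=%s span=1", chrom), con)
    writeLines(sprintf("%d\t%.6g", rows$center, rows$t_stat), con)
  }
  invisible(out_path)
}

# [alignment filename]_[datestamp]_[timestamp].{txt,wig}; the stamp can be
# frozen for reproducible output names
output_basename <- function(alignment_path, stamp = NULL) {
  if (is.null(stamp)) {
    now <- Sys.time()
    stamp <- format(now, "%Y%m%d_%H%M%S")
  }
  paste0(basename(alignment_path), "_", stamp)
}
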