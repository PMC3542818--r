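#' Construct a read set
#'
#' A read set reduces each aligned single-end read to the triple
#' (chromosome, 5' end, strand). Coordinates are 1-based inclusive. For a
#' reverse-strand alignment the 5' end is the rightmost aligned reference
#' base: a minus-strand alignment starts at the 3' end of the reference and
#' extends left, so its biological 5' position is its rightmost coordinate.
#'
#' @param chrom Character vector of reference names.
#' @param pos5 Integer vector of 1-based 5'-end coordinates.
#' @param strand Character vector, `"+"` or `"-"`.
#' @param genome Optional `genome_table`; when given, coordinates are
#'   validated against chromosome bounds.
#' @return A data.frame of class `read_set` with columns
#'   `chrom`, `pos5`, `strand`.
#' @export
read_set <- function(chrom, pos5, strand, genome = NULL) {
  chrom <- as.character(chrom)
  pos5 <- as.integer(pos5)
  strand <- as.character(strand)
  n <- length(chrom)
  if (length(pos5) != n || length(strand) != n) {
    stop("chrom, pos5 and strand must have equal length")
  }
  if (n > 0L && !all(strand %in% c("+", "-"))) {
    stop("strand must be '+' or '-'")
  }
  if (n > 0L && any(pos5 < 1L)) stop("pos5 must be >= 1")
  if (!is.null(genome)) {
    unknown <- !(chrom %in% names(genome))
    if (any(unknown)) stop("reads on unknown reference: ", chrom[unknown][1])
    if (any(pos5 > unclass(genome)[chrom])) {
      stop("pos5 beyond chromosome length")
    }
  }
  structure(
    data.frame(chrom = chrom, pos5 = pos5, strand = strand,
               stringsAsFactors = FALSE),
    class = c("read_set", "data.frame")
  )
}

# reference-space width of a CIGAR string: sum of M/D/N/=/X operation lengths
cigar_reference_width <- function(cigar) {
  GenomicAlignments::cigarWidthAlongReferenceSpace(cigar)
}

#' Read single-end alignments from BAM, SAM, or BED
#'
#' Each mapped, primary, non-supplementary record yields one read reduced to
#' (chromosome, 5' end, strand). For SAM/BAM, a forward record's 5' end is its
#' leftmost aligned coordinate (POS) and a reverse record's 5' end is its
#' rightmost aligned coordinate (POS + reference width of CIGAR - 1). For BED
#' (0-based half-open, strand in column 6), a forward read's 5' end is
#' `chromStart + 1` and a reverse read's is `chromEnd`. Reads on references
#' absent from `genome` are skipped with a warning. BED records are never
#' MAPQ-filtered.
#'
#' @param path Path to the alignment file.
#' @param format One of `"bam"`, `"sam"`, `"bed"`; default guesses from the
#'   file extension.
#' @param genome A `genome_table` covering the references used.
#' @param min_mapq Drop SAM/BAM records with mapping quality below this
#'   (default 0, i.e. no filter; records with missing MAPQ are kept).
#' @return A `read_set`.
#' @export
read_alignments <- function(path, format = c("auto", "bam", "sam", "bed"),
                            genome, min_mapq = 0L) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    if (!ext %in% c("bam", "sam", "bed")) {
      stop("cannot guess format from extension '", ext,
           "'; pass format explicitly")
    }
    format <- ext
  }
  if (!file.exists(path)) stop("alignment file not found: ", path)
  if (!inherits(genome, "genome_table")) stop("genome must be a genome_table")

  reads <- switch(format,
    bed = read_bed_alignments(path),
    sam = ,
    bam = read_bam_alignments(path, format, min_mapq)
  )

  keep <- reads$chrom %in% names(genome)
  if (!all(keep)) {
    skipped <- unique(reads$chrom[!keep])
    warning("skipping ", sum(!keep), " reads on references absent from the ",
            "genome table: ", paste(utils::head(skipped, 5), collapse = ", "))
    reads <- reads[keep, , drop = FALSE]
  }
  clen <- unclass(genome)[reads$chrom]
  bad <- reads$pos5 < 1L | reads$pos5 > clen
  if (any(bad)) {
    warning("dropping ", sum(bad), " reads with 5' ends outside chromosome ",
            "bounds")
    reads <- reads[!bad, , drop = FALSE]
  }
  read_set(reads$chrom, reads$pos5, reads$strand)
}

read_bed_alignments <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  lines <- lines[!grepl("^(track|browser|#)", lines)]
  if (length(lines) == 0L) {
    return(data.frame(chrom = character(), pos5 = integer(),
                      strand = character(), stringsAsFactors = FALSE))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncol <- lengths(fields)
  if (any(ncol < 6L)) {
    stop("BED line ", which(ncol < 6L)[1],
         " has fewer than 6 columns; strand (column 6) is required")
  }
  chrom <- vapply(fields, `[[`, "", 1L)
  start0 <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 2L)))
  end0 <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 3L)))
  strand <- vapply(fields, `[[`, "", 6L)
  bad <- is.na(start0) | is.na(end0) | end0 <= start0 |
    !(strand %in% c("+", "-"))
  if (any(bad)) {
    stop("malformed BED record at line ", which(bad)[1], ": ",
         lines[which(bad)[1]])
  }
  pos5 <- ifelse(strand == "+", start0 + 1L, end0)
  data.frame(chrom = chrom, pos5 = as.integer(pos5), strand = strand,
             stringsAsFactors = FALSE)
}

read_bam_alignments <- function(path, format, min_mapq) {
  bam <- path
  if (format == "sam") {
    dest <- tempfile(fileext = "")
    bam <- Rsamtools::asBam(path, destination = dest, overwrite = TRUE,
                            indexDestination = FALSE)
  }
  flag <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                 isSecondaryAlignment = FALSE,
                                 isSupplementaryAlignment = FALSE)
  param <- Rsamtools::ScanBamParam(
    flag = flag,
    what = c("rname", "pos", "strand", "mapq", "cigar")
  )
  rec <- Rsamtools::scanBam(bam, param = param)[[1]]
  chrom <- as.character(rec$rname)
  strand <- as.character(rec$strand)
  keep <- strand %in% c("+", "-") & !is.na(rec$pos)
  if (min_mapq > 0L) keep <- keep & (is.na(rec$mapq) | rec$mapq >= min_mapq)
  chrom <- chrom[keep]
  strand <- strand[keep]
  pos <- rec$pos[keep]
  cigar <- rec$cigar[keep]
  pos5 <- pos
  rev <- strand == "-"
  if (any(rev)) {
    pos5[rev] <- pos[rev] + cigar_reference_width(cigar[rev]) - 1L
  }
  data.frame(chrom = chrom, pos5 = as.integer(pos5), strand = strand,
             stringsAsFactors = FALSE)
}
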