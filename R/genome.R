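#' Load a chromosome-lengths table
#'
#' Reads a two-column tab-separated file mapping reference-sequence names to
#' chromosome lengths in base pairs. This table is used to preallocate the
#' per-chromosome probability landscape and to bound read coordinates.
#'
#' @param path Path to a TSV file: column 1 = reference name (e.g. `chr1`),
#'   column 2 = length in bp (digits only, no thousands separators).
#' @return A `genome_table`: a named integer-ish numeric vector of lengths,
#'   in file order.
#' @examples
#' tf <- tempfile()
#' writeLines("chrI\t230218", tf)
#' load_chrom_lengths(tf)
#' @export
load_chrom_lengths <- function(path) {
  if (!file.exists(path)) {
    stop("chromosome-lengths file not found: ", path)
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    stop("chromosome-lengths file is empty: ", path)
  }
  nm <- character(length(lines))
  len <- numeric(length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(f) < 2L || !nzchar(f[[1]]) || !grepl("^[0-9]+$", f[[2]])) {
      stop("malformed chromosome-lengths line ", i, ": ", lines[[i]])
    }
    nm[i] <- f[[1]]
    len[i] <- as.numeric(f[[2]])
  }
  if (anyDuplicated(nm)) {
    stop("duplicate reference name in chromosome-lengths file: ",
         nm[duplicated(nm)][1])
  }
  if (any(len <= 0)) stop("chromosome lengths must be strictly positive")
  genome_table(stats::setNames(len, nm))
}

#' Construct a genome table from a named vector of lengths
#'
#' @param lengths Named numeric vector; names are reference-sequence names,
#'   values are chromosome lengths in bp.
#' @return A `genome_table` object.
#' @export
genome_table <- function(lengths) {
  if (is.null(names(lengths)) || any(!nzchar(names(lengths)))) {
    stop("genome table requires named lengths")
  }
  if (anyDuplicated(names(lengths))) stop("duplicate reference names")
  nm <- names(lengths)
  lengths <- as.numeric(lengths)
  names(lengths) <- nm
  if (any(!is.finite(lengths)) || any(lengths <= 0) ||
      any(lengths != floor(lengths))) {
    stop("chromosome lengths must be positive integers")
  }
  structure(lengths, class = "genome_table")
}

#' @export
print.genome_table <- function(x, ...) {
  cat("genome_table with", length(x), "sequences,",
      format(sum(x), big.mark = ","), "bp total\n")
  invisible(x)
}

#' Built-in genome presets
#'
#' Chromosome-length tables for common assemblies ship with the package, so
#' runs against ce10, mm9, mm10, hg18, or hg19 do not need a user-supplied
#' lengths file.
#'
#' @param name One of `"ce10"`, `"mm9"`, `"mm10"`, `"hg18"`, `"hg19"`.
#' @return A `genome_table`.
#' @export
genome_preset <- function(name = c("ce10", "mm9", "mm10", "hg18", "hg19")) {
  name <- match.arg(name)
  path <- system.file("extdata", "genomes", paste0(name, ".tsv"),
                      package = "nucleoscan", mustWork = TRUE)
  load_chrom_lengths(path)
}
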