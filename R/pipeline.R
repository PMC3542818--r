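#' Scan configuration
#'
#' Bundles every tunable of the detection pipeline with its default.
#'
#' @param W Scan-window width in bp (default 200).
#' @param A_w,B_w,C_w Sub-window widths (defaults 75/50/75); must sum to `W`.
#' @param t_c Triangle-statistic cutoff (default 1.7, low enough to keep every
#'   nucleosome that later clears the FDR filter).
#' @param F FDR cutoff in \[0, 1\] (default 0.01).
#' @param S Number of shaking simulations (default 3; larger S tightens the
#'   FDR estimates).
#' @param threads Worker-pool size (default 1).
#' @param alpha,beta_param Beta shapes of the read-to-center offset model.
#' @param seed Master seed for all stochastic stages.
#' @param min_mapq Minimum mapping quality for SAM/BAM records (default 0).
#' @param target_interval Chunk core size in bp for the scanning plan.
#' @return A `scan_config` list.
#' @export
scan_config <- function(W = 200L, A_w = 75L, B_w = 50L, C_w = 75L,
                        t_c = 1.7, F = 0.01, S = 3L, threads = 1L,
                        alpha = 1.9204, beta_param = 1.8937, seed = 1L,
                        min_mapq = 0L, target_interval = 1e6) {
  if (t_c <= 0) stop("t_c must be positive")
  if (F < 0 || F > 1) stop("F must lie in [0, 1]")
  if (S < 1L) stop("S must be >= 1")
  if (threads < 1L) stop("threads must be >= 1")
  structure(list(partition = window_partition(W, A_w, B_w, C_w),
                 t_c = t_c, F = F, S = as.integer(S),
                 threads = as.integer(threads),
                 alpha = alpha, beta_param = beta_param,
                 seed = as.integer(seed), min_mapq = as.integer(min_mapq),
                 target_interval = target_interval),
            class = "scan_config")
}

#' Run the full nucleosome-detection pipeline
#'
#' Reads alignments, builds the center-probability landscape per chromosome,
#' scans it with the triangle statistic, decorrelates calls with the
#' N-statistic, estimates per-candidate FDRs by read shaking, filters by the
#' FDR cutoff, and writes the TXT centers table and the WIG track next to
#' `out_dir`. Output names follow
#' `[alignment filename]_[datestamp]_[timestamp].{txt,wig}`; pass `stamp` to
#' freeze the date/time part for reproducible names.
#'
#' @param alignment_path Path to a BAM, SAM, or BED alignment file.
#' @param genome A `genome_table`, or the name of a built-in preset.
#' @param config A `scan_config`.
#' @param out_dir Output directory (default: directory of the alignment
#'   file).
#' @param format Alignment format (default guessed from the extension).
#' @param stamp Optional fixed stamp string replacing the
#'   datestamp_timestamp pair in output names.
#' @param quiet Suppress progress messages.
#' @return List with `txt_path`, `wig_path`, `candidates` (the filtered
#'   `candidate_set`), `fdr_table`, and `summary`.
#' @export
run_pipeline <- function(alignment_path, genome, config = scan_config(),
                         out_dir = dirname(alignment_path),
                         format = "auto", stamp = NULL, quiet = FALSE) {
  stopifnot(inherits(config, "scan_config"))
  t0 <- Sys.time()
  if (is.character(genome)) genome <- genome_preset(genome)
  say <- function(...) if (!quiet) message(...)

  reads <- read_alignments(alignment_path, format, genome,
                           min_mapq = config$min_mapq)
  say("read ", nrow(reads), " alignments from ", alignment_path)

  pmf <- beta_offset_pmf(config$alpha, config$beta_param)
  cands <- detect_candidates(reads, genome, pmf, config$partition,
                             config$t_c, threads = config$threads,
                             target_interval = config$target_interval)
  cands <- order_candidates(cands, genome)
  say(nrow(cands), " candidate nucleosomes before FDR filtering")

  fdr_table <- estimate_fdr(cands, reads, genome, pmf, config$partition,
                            config$t_c, S = config$S, seed = config$seed,
                            threads = config$threads,
                            target_interval = config$target_interval)
  kept <- filter_candidates(cands, fdr_table, config$F)
  say(nrow(kept), " candidates at FDR <= ", config$F)

  base <- output_basename(alignment_path, stamp)
  txt_path <- file.path(out_dir, paste0(base, ".txt"))
  wig_path <- file.path(out_dir, paste0(base, ".wig"))
  write_centers_txt(kept, txt_path)
  write_wig(kept, wig_path)

  elapsed <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  say(sprintf("done in %.1f s; wrote %s and %s", elapsed, txt_path, wig_path))
  list(txt_path = txt_path, wig_path = wig_path, candidates = kept,
       fdr_table = fdr_table,
       summary = list(n_reads = nrow(reads),
                      n_candidates = nrow(cands),
                      n_kept = nrow(kept),
                      elapsed_sec = elapsed))
}
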