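
fmt_pct <- function(x) ifelse(is.na(x), "NA", sprintf("%.1f", x))

fmt_indel_size <- function(s) ifelse(s > 0L, sprintf("+%d", s), sprintf("%d", s))

fmt_ratio <- function(x) ifelse(is.na(x), "NA", sprintf("%.2f", x))

#' Build the master-summary table for a run
#'
#' One row per sample, in discovery order. Columns: `Name`, `Total_reads`,
#' `Seq_matches`; a combined `reads(percent)` cell per test sequence; the
#' ranked indel columns `#k-Indel` / `#k-Reads(%)` for `k = 1..top_indels`
#' (empty, not zero, when fewer distinct indel sizes exist); `Total_indel`;
#' the QC ratios `SNP_test` and `raw_wt_test`; and a trailing percent-only
#' column per test sequence (`<test>_pct`) so the file sorts cleanly in a
#' spreadsheet. Percentages print with 1 decimal; undefined values print as
#' `NA`.
#'
#' @param results list of [tally_sample()] results in discovery order
#' @param config a [run_config()]
#' @return data.frame of character cells, one row per sample
#' @export
build_master_table <- function(results, config) {
  tests <- names(config$test_list)
  k <- config$top_indels
  cols <- c("Name", "Total_reads", "Seq_matches", tests,
            as.vector(rbind(paste0("#", seq_len(k), "-Indel"),
                            paste0("#", seq_len(k), "-Reads(%)"))),
            "Total_indel", "SNP_test", "raw_wt_test",
            paste0(tests, "_pct"))
  rows <- lapply(results, function(r) {
    tf <- test_sequence_frequencies(r)
    ri <- rank_indels(r, k)
    qc <- compute_qc(r, config)
    indel_cells <- character(2L * k)
    if (nrow(ri) > 0L) {
      for (i in seq_len(nrow(ri))) {
        indel_cells[2L * i - 1L] <- fmt_indel_size(ri$indel_size[i])
        indel_cells[2L * i] <- sprintf("%d(%s)", ri$reads[i],
                                       fmt_pct(ri$percent[i]))
      }
    }
    c(r$name,
      as.character(r$total_reads),
      as.character(r$seq_match_count),
      sprintf("%d(%s)", tf$reads, fmt_pct(tf$percent)),
      indel_cells,
      fmt_pct(total_indel(r)),
      fmt_ratio(qc$snp_test),
      fmt_ratio(qc$raw_wt_test),
      fmt_pct(tf$percent))
  })
  m <- do.call(rbind, c(rows, list(matrix(character(0), 0L, length(cols)))))
  df <- as.data.frame(m, stringsAsFactors = FALSE)
  names(df) <- cols
  df
}

#' Write the master-summary CSV
#'
#' Writes `<out_dir>/<run_id>/<run_id>.csv` (RFC 4180, UTF-8, LF), header
#' row first, one row per sample in discovery order. A run with no samples
#' yields a header-only file.
#'
#' @param results list of [tally_sample()] results
#' @param config a [run_config()]
#' @param out_dir parent output directory
#' @return the CSV path, invisibly
#' @export
write_master_csv <- function(results, config, out_dir = ".") {
  dir <- file.path(out_dir, config$run_id)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) stop("cannot create output directory: ", dir, call. = FALSE)
  path <- file.path(dir, paste0(config$run_id, ".csv"))
  df <- build_master_table(results, config)
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE, eol = "\n",
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Write the top-reads TXT report
#'
#' Writes `<out_dir>/<run_id>/<run_id>.txt`. For each sample: a header line
#' with the sample name, then up to `top_reads` lines of
#' `ANCHORED_SEQUENCE, count` — exact flank-to-flank read bins in
#' descending count order, ties broken lexicographically by sequence —
#' followed by a blank line. Binning on exact sequence makes true alleles
#' visually separable from low-count PCR/sequencing-error bins.
#'
#' @inheritParams write_master_csv
#' @return the TXT path, invisibly
#' @export
write_top_reads_txt <- function(results, config, out_dir = ".") {
  dir <- file.path(out_dir, config$run_id)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) stop("cannot create output directory: ", dir, call. = FALSE)
  path <- file.path(dir, paste0(config$run_id, ".txt"))
  lines <- character(0)
  for (r in results) {
    lines <- c(lines, r$name)
    bins <- r$read_bins
    if (length(bins)) {
      seqs <- names(bins)
      counts <- as.integer(bins)
      ord <- order(-counts, seqs, method = "radix")
      keep <- ord[seq_len(min(config$top_reads, length(ord)))]
      lines <- c(lines, sprintf("%s, %d", seqs[keep], counts[keep]))
    }
    lines <- c(lines, "")
  }
  writeLines(lines, path, sep = "\n")
  invisible(path)
}

#' Analyze a directory of FASTQ files
#'
#' The whole pipeline in one call: resolve the reference frame, discover the
#' samples, tally each, and (optionally) write the master-summary CSV and
#' top-reads TXT into `<out_dir>/<run_id>/`.
#'
#' @param config a [run_config()] with `fastq_dir` set
#' @param out_dir parent output directory; `NULL` skips writing files
#' @param quiet suppress per-sample progress messages
#' @return object of class `run_report`: list with `config`, `frame`,
#'   `results` (per-sample tallies in discovery order), `table` (the master
#'   summary as a data.frame), and the written `csv_path` / `txt_path` (or
#'   `NULL`).
#' @export
analyze_run <- function(config, out_dir = ".", quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  frame <- establish_reference(config)
  samples <- discover_samples(config$fastq_dir)
  if (nrow(samples) == 0L && !quiet) {
    warning("no FASTQ files found in ", config$fastq_dir, call. = FALSE)
  }
  results <- vector("list", nrow(samples))
  for (i in seq_len(nrow(samples))) {
    results[[i]] <- tally_sample(samples[i, ], config, frame)
    if (!quiet) {
      message(sprintf("[%s] %d reads, %d seq_matches",
                      results[[i]]$name, results[[i]]$total_reads,
                      results[[i]]$seq_match_count))
    }
  }
  csv_path <- txt_path <- NULL
  if (!is.null(out_dir)) {
    csv_path <- write_master_csv(results, config, out_dir)
    txt_path <- write_top_reads_txt(results, config, out_dir)
  }
  structure(list(config = config, frame = frame, results = results,
                 table = build_master_table(results, config),
                 csv_path = csv_path, txt_path = txt_path),
            class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat("Amplicon editing run '", x$config$run_id, "': ",
      length(x$results), " sample(s)\n", sep = "")
  if (!is.null(x$csv_path)) cat("  CSV: ", x$csv_path, "\n", sep = "")
  if (!is.null(x$txt_path)) cat("  TXT: ", x$txt_path, "\n", sep = "")
  if (length(x$results)) {
    show <- x$table[, c("Name", "Total_reads", "Seq_matches", "Total_indel",
                        "SNP_test", "raw_wt_test")]
    print(show, row.names = FALSE)
  }
  invisible(x)
}

#' @export
summary.run_report <- function(object, ...) {
  total_reads <- sum(vapply(object$results, `[[`, integer(1), "total_reads"))
  total_matches <- sum(vapply(object$results, `[[`, integer(1),
                              "seq_match_count"))
  cat("Run '", object$config$run_id, "': ", length(object$results),
      " sample(s), ", total_reads, " reads, ", total_matches,
      " seq_matches\n", sep = "")
  flagged <- Filter(function(r) length(compute_qc(r, object$config)$flags) > 0,
                    object$results)
  if (length(flagged)) {
    cat("QC flags:\n")
    for (r in flagged) {
      cat("  ", r$name, ": ",
          paste(compute_qc(r, object$config)$flags, collapse = "; "),
          "\n", sep = "")
    }
  }
  invisible(object$table)
}
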