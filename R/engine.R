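
# first occurrence (1-based) of fixed pattern in each string; -1 if absent
first_fixed <- function(pattern, x) {
  as.integer(regexpr(pattern, x, fixed = TRUE))
}

count_fixed <- function(pattern, x) {
  m <- gregexpr(pattern, x, fixed = TRUE)[[1L]]
  if (m[1L] == -1L) 0L else length(m)
}

#' Establish the wild-type reference frame
#'
#' Locates the two flanking anchors in the reference amplicon and measures
#' the wild-type inner length: the number of bases strictly between the end
#' of `seq_start` and the start of `seq_end`. Every read's indel size is the
#' difference between its own inner length and this reference length. Each
#' anchor must occur exactly once in `ref_seq` — a repeated anchor would make
#' the frame ambiguous and is rejected outright.
#'
#' @param config a [run_config()]
#' @return object of class `reference_frame`: list with `start_pos` and
#'   `end_pos` (0-based offsets of the anchor occurrences in `ref_seq`) and
#'   `wt_inner_len`.
#' @export
establish_reference <- function(config) {
  stopifnot(inherits(config, "run_config"))
  for (flank in c("seq_start", "seq_end")) {
    k <- count_fixed(config[[flank]], config$ref_seq)
    if (k == 0L) stop(flank, " not found in ref_seq", call. = FALSE)
    if (k > 1L) stop(flank, " occurs ", k,
                     " times in ref_seq; reference frame is ambiguous",
                     call. = FALSE)
  }
  s1 <- first_fixed(config$seq_start, config$ref_seq)   # 1-based
  s2 <- first_fixed(config$seq_end, config$ref_seq)
  start_end <- s1 + nchar(config$seq_start)             # first base after seq_start
  if (s2 < start_end) {
    stop("seq_end overlaps or precedes seq_start in ref_seq", call. = FALSE)
  }
  structure(list(start_pos = s1 - 1L, end_pos = s2 - 1L,
                 wt_inner_len = s2 - start_end),
            class = "reference_frame")
}

#' Classify a single read against the anchors
#'
#' Searches the read for `seq_start` (first occurrence) and then `seq_end`
#' (first occurrence strictly after the end of the `seq_start` match). A read
#' containing both in that order is a *seq_match*; its anchored region runs
#' from the first base of the `seq_start` match through the last base of the
#' `seq_end` match, and its indel size is the inner length minus the
#' wild-type inner length (negative = deletion, positive = insertion).
#' Ambiguity codes (`N`) never match an anchor. Reads where `seq_end` only
#' occurs before or overlapping `seq_start` (e.g. inverted amplicons) are
#' non-matches, not errors.
#'
#' @param sequence one read sequence (uppercase)
#' @param config a [run_config()]
#' @param frame the [establish_reference()] result
#' @return `NULL` for a non-match, else a list of class `seq_match` with
#'   `anchored_region`, `inner_len`, `indel_size`.
#' @export
match_read <- function(sequence, config, frame) {
  s <- first_fixed(config$seq_start, sequence)
  if (s == -1L) return(NULL)
  after <- s + nchar(config$seq_start)                  # 1-based pos after anchor
  rest <- substr(sequence, after, nchar(sequence))
  e_rel <- first_fixed(config$seq_end, rest)
  if (e_rel == -1L) return(NULL)
  inner_len <- e_rel - 1L
  region <- substr(sequence, s, after + inner_len + nchar(config$seq_end) - 1L)
  structure(list(anchored_region = region, inner_len = inner_len,
                 indel_size = inner_len - frame$wt_inner_len),
            class = "seq_match")
}

# Vectorized classification of many reads; returns list(matched, inner_len,
# anchored_region) with matched a logical vector over the input.
classify_reads <- function(sequences, config, frame) {
  s <- first_fixed(config$seq_start, sequences)
  has_start <- s != -1L
  inner_len <- rep(NA_integer_, length(sequences))
  region <- rep(NA_character_, length(sequences))
  if (any(has_start)) {
    after <- s[has_start] + nchar(config$seq_start)
    rest <- substr(sequences[has_start], after, nchar(sequences[has_start]))
    e_rel <- first_fixed(config$seq_end, rest)
    ok <- e_rel != -1L
    il <- e_rel[ok] - 1L
    idx <- which(has_start)[ok]
    inner_len[idx] <- il
    region[idx] <- substr(sequences[idx], s[idx],
                          after[ok] + il + nchar(config$seq_end) - 1L)
  }
  list(matched = !is.na(inner_len), inner_len = inner_len,
       anchored_region = region)
}

#' Tally one sample's reads
#'
#' Single pass over a sample's reads accumulating everything the reports
#' need: total read count, seq_match count, the indel-size histogram, exact
#' anchored-region read bins, per-test-sequence counts (each seq_match counts
#' at most once per test), and the raw-read counters behind the QC ratios
#' (reads containing `seq_start`, reads containing `seq_end`, and raw reads
#' containing the first test sequence).
#'
#' @param sample either one row of [discover_samples()] (list/data.frame with
#'   `name` and `path`) or a character vector of read sequences (then `name`
#'   must be given).
#' @param config a [run_config()]
#' @param frame the [establish_reference()] result
#' @param name sample name when `sample` is a raw sequence vector
#' @return object of class `sample_result`
#' @export
tally_sample <- function(sample, config, frame, name = NULL) {
  if (is.character(sample) && is.null(dim(sample))) {
    seqs <- toupper(sample)
    if (is.null(name)) stop("name is required when tallying raw sequences",
                            call. = FALSE)
  } else {
    name <- sample$name
    seqs <- read_fastq(sample$path)$sequence
  }
  cls <- classify_reads(seqs, config, frame)
  m <- cls$matched
  indel_sizes <- cls$inner_len[m] - frame$wt_inner_len
  regions <- cls$anchored_region[m]

  indel_hist <- integer(0)
  read_bins <- integer(0)
  if (length(indel_sizes)) {
    th <- table(indel_sizes)
    indel_hist <- stats::setNames(as.integer(th), names(th))
    tb <- table(regions)
    read_bins <- stats::setNames(as.integer(tb), names(tb))
  }

  scope <- if (config$test_match_scope == "raw_read") seqs[m] else regions
  test_counts <- vapply(config$test_list, function(t) {
    sum(first_fixed(t, scope) != -1L)
  }, integer(1))

  structure(list(
    name = name,
    total_reads = length(seqs),
    seq_match_count = sum(m),
    indel_hist = indel_hist,
    read_bins = read_bins,
    test_counts = test_counts,
    start_hits = sum(first_fixed(config$seq_start, seqs) != -1L),
    end_hits = sum(first_fixed(config$seq_end, seqs) != -1L),
    raw_test1_hits = sum(first_fixed(config$test_list[[1L]], seqs) != -1L)
  ), class = "sample_result")
}

#' @export
print.sample_result <- function(x, ...) {
  cat("Sample '", x$name, "': ", x$total_reads, " reads, ",
      x$seq_match_count, " seq_matches", sep = "")
  if (x$seq_match_count > 0L) {
    cat(", Total_indel ", sprintf("%.1f", total_indel(x)), "%", sep = "")
  }
  cat("\n")
  invisible(x)
}

#' Per-sample indel-size frequencies
#'
#' Frequency of each observed indel size among seq_matches:
#' `count / seq_match_count * 100`. Undefined (all `NA`) when the sample has
#' no seq_matches.
#'
#' @param result a [tally_sample()] result
#' @return named numeric vector, names are indel sizes in bp; values sum to
#'   100 up to rounding.
#' @export
indel_frequencies <- function(result) {
  if (result$seq_match_count == 0L) {
    return(stats::setNames(rep(NA_real_, length(result$indel_hist)),
                           names(result$indel_hist)))
  }
  result$indel_hist / result$seq_match_count * 100
}

#' Percentage of seq_matches that are not of wild-type length
#'
#' Reads whose inter-anchor length differs from the reference length carry
#' an indel of nonzero size; this reports their share of all seq_matches.
#'
#' @param result a [tally_sample()] result
#' @return percentage in \[0, 100\]; `NA` when the sample has no seq_matches.
#' @export
total_indel <- function(result) {
  n <- result$seq_match_count
  if (n == 0L) return(NA_real_)
  wt <- if ("0" %in% names(result$indel_hist)) result$indel_hist[["0"]] else 0L
  100 * (n - wt) / n
}

#' Rank indel sizes by read count
#'
#' Orders observed indel sizes by read count (descending); ties are broken by
#' absolute size ascending, then deletion before insertion. At most `n`
#' entries are returned (fewer when fewer distinct sizes were observed).
#'
#' @param result a [tally_sample()] result
#' @param n maximum number of ranks (defaults to the run's `top_indels`)
#' @return data.frame with columns `rank`, `indel_size`, `reads`, `percent`
#' @export
rank_indels <- function(result, n = 8L) {
  h <- result$indel_hist
  if (length(h) == 0L) {
    return(data.frame(rank = integer(0), indel_size = integer(0),
                      reads = integer(0), percent = numeric(0)))
  }
  sizes <- as.integer(names(h))
  counts <- as.integer(h)
  ord <- order(-counts, abs(sizes), sizes)
  keep <- ord[seq_len(min(n, length(ord)))]
  data.frame(rank = seq_along(keep),
             indel_size = sizes[keep],
             reads = counts[keep],
             percent = if (result$seq_match_count > 0L)
               counts[keep] / result$seq_match_count * 100 else NA_real_)
}

#' Per-test-sequence read counts and frequencies
#'
#' Each test sequence is quantified independently as the share of seq_matches
#' containing it; tests may overlap, so percentages need not sum to 100 or
#' less.
#'
#' @param result a [tally_sample()] result
#' @return data.frame with columns `test`, `reads`, `percent` in the order of
#'   the run's `test_list`; `percent` is `NA` when there are no seq_matches.
#' @export
test_sequence_frequencies <- function(result) {
  n <- result$seq_match_count
  data.frame(test = names(result$test_counts),
             reads = as.integer(result$test_counts),
             percent = if (n > 0L) result$test_counts / n * 100 else
               rep(NA_real_, length(result$test_counts)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Quality-control ratios for one sample
#'
#' `snp_test` is the ratio of raw reads containing the upstream anchor to raw
#' reads containing the downstream anchor. A SNP (or large indel) knocking
#' out one anchor on one of two equal alleles halves one side, giving 0.5 or
#' 2.0; deviations from 1 flag allele dropout. `raw_wt_test` is the ratio of
#' raw reads containing the first test sequence to seq_matches containing
#' it; values well above 1 flag alleles whose reads lost both anchors. Both
#' ratios report 0 when numerator and denominator are both 0 (the expected
#' outcome for a total knockout clone when the first test is the wild-type
#' gRNA site) and are undefined (`NA`, flagged) when only the denominator
#' is 0. A defined `raw_wt_test` below 1 is flagged, not fatal, since the
#' raw-read superset should contain the seq_match subset.
#'
#' @param result a [tally_sample()] result
#' @param config a [run_config()]
#' @return list of class `qc_ratios` with `snp_test`, `raw_wt_test`, and a
#'   character vector `flags`
#' @export
compute_qc <- function(result, config) {
  ratio <- function(num, den) {
    if (den == 0L) {
      if (num == 0L) 0 else NA_real_
    } else num / den
  }
  first_test <- names(config$test_list)[1L]
  snp <- ratio(result$start_hits, result$end_hits)
  rwt <- ratio(result$raw_test1_hits, result$test_counts[[first_test]])
  flags <- character(0)
  if (is.na(snp)) flags <- c(flags, "snp_test undefined (no seq_end hits)")
  if (is.na(rwt)) {
    flags <- c(flags, "raw_wt_test undefined (first test absent from seq_matches)")
  } else if (result$test_counts[[first_test]] > 0L && rwt < 1) {
    flags <- c(flags, "raw_wt_test < 1 (seq_match hits exceed raw hits)")
  }
  structure(list(snp_test = snp, raw_wt_test = rwt, flags = flags),
            class = "qc_ratios")
}
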