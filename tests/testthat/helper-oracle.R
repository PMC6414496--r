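# Independent brute-force oracle: re-scans every read one at a time using
# gregexpr over all occurrences, never the package's vectorized path.
oracle_tally <- function(seqs, cfg, frame) {
  all_occ <- function(pattern, x) {
    m <- gregexpr(pattern, x, fixed = TRUE)[[1L]]
    if (m[1L] == -1L) integer(0) else as.integer(m)
  }
  regions <- character(0)
  indels <- integer(0)
  start_hits <- end_hits <- raw1 <- 0L
  n_match <- 0L
  test_counts <- setNames(integer(length(cfg$test_list)),
                          names(cfg$test_list))
  for (read in toupper(seqs)) {
    so <- all_occ(cfg$seq_start, read)
    eo <- all_occ(cfg$seq_end, read)
    if (length(so)) start_hits <- start_hits + 1L
    if (length(eo)) end_hits <- end_hits + 1L
    if (length(all_occ(cfg$test_list[[1L]], read))) raw1 <- raw1 + 1L
    if (length(so) == 0L) next
    s <- so[1L]
    after <- s + nchar(cfg$seq_start)
    eo <- eo[eo >= after]
    if (length(eo) == 0L) next
    e <- eo[1L]
    n_match <- n_match + 1L
    region <- substr(read, s, e + nchar(cfg$seq_end) - 1L)
    regions <- c(regions, region)
    indels <- c(indels, (e - after) - frame$wt_inner_len)
    scope <- if (cfg$test_match_scope == "raw_read") read else region
    for (t in names(cfg$test_list)) {
      if (length(all_occ(cfg$test_list[[t]], scope))) {
        test_counts[[t]] <- test_counts[[t]] + 1L
      }
    }
  }
  hist <- if (length(indels)) {
    tb <- table(indels)
    setNames(as.integer(tb), names(tb))
  } else integer(0)
  bins <- if (length(regions)) {
    tb <- table(regions)
    setNames(as.integer(tb), names(tb))
  } else integer(0)
  list(total_reads = length(seqs), seq_match_count = n_match,
       indel_hist = hist, read_bins = bins, test_counts = test_counts,
       start_hits = start_hits, end_hits = end_hits, raw_test1_hits = raw1)
}

expect_matches_oracle <- function(result, oracle) {
  testthat::expect_equal(result$total_reads, oracle$total_reads)
  testthat::expect_equal(result$seq_match_count, oracle$seq_match_count)
  testthat::expect_equal(result$indel_hist[order(as.integer(names(result$indel_hist)))],
                         oracle$indel_hist[order(as.integer(names(oracle$indel_hist)))])
  testthat::expect_equal(result$read_bins[order(names(result$read_bins))],
                         oracle$read_bins[order(names(oracle$read_bins))])
  testthat::expect_equal(result$test_counts, oracle$test_counts)
  testthat::expect_equal(result$start_hits, oracle$start_hits)
  testthat::expect_equal(result$end_hits, oracle$end_hits)
  testthat::expect_equal(result$raw_test1_hits, oracle$raw_test1_hits)
}
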