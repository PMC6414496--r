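test_that("reference frame measures the inter-anchor wild-type length", {
  cfg <- run_config("x", "AAACCCTTTGGGAAATTTCCCGGG", "AAACCC", "CCCGGG",
                    list(t1 = "TTTGGG"))
  fr <- establish_reference(cfg)
  expect_equal(fr$wt_inner_len, 12L)
  expect_equal(fr$start_pos, 0L)
  expect_equal(fr$end_pos, 18L)

  abut <- run_config("x", "TTAAACCCGGGTT", "AAACC", "CGGG", list(t1 = "AC"))
  expect_equal(establish_reference(abut)$wt_inner_len, 0L)
})

test_that("ambiguous, absent or misordered anchors are fatal", {
  mk <- function(ref, s, e) run_config("x", ref, s, e, list(t1 = "ACGT"))
  expect_error(establish_reference(mk("AAATTTAAATTTCCC", "AAA", "CCC")),
               "seq_start occurs 2 times")
  expect_error(establish_reference(mk("AAATTTCCC", "GGG", "CCC")),
               "seq_start not found")
  expect_error(establish_reference(mk("AAATTTCCC", "AAA", "GGG")),
               "seq_end not found")
  expect_error(establish_reference(mk("CCCTTTAAA", "AAA", "CCC")),
               "overlaps or precedes")
})

test_that("reads are classified by inter-anchor length difference", {
  cfg <- toy_config()
  fr <- toy_frame(cfg)

  m <- match_read(toy$ref, cfg, fr)
  expect_s3_class(m, "seq_match")
  expect_equal(m$indel_size, 0L)
  expect_equal(m$inner_len, 60L)
  expect_equal(nchar(m$anchored_region),
               nchar(toy$seq_start) + 60L + nchar(toy$seq_end))

  expect_equal(match_read(mutate_allele(toy$ref, toy$cut, 3), cfg, fr)$indel_size, -3L)
  # 34-bp loxP + 6-bp BamHI knock-in scores as a +40 bp insertion
  expect_equal(match_read(toy$alleles$loxp_ins, cfg, fr)$indel_size, 40L)

  expect_null(match_read(substr(toy$ref, 1, 60), cfg, fr))   # seq_end lost
  expect_null(match_read(gsub("GATTACAGGT", "GATTANAGGT", toy$ref), cfg, fr))
  # inverted layout: downstream anchor only before upstream anchor
  inverted <- paste0(toy$seq_end, "TTTT", toy$seq_start, "AAAA")
  expect_null(match_read(inverted, cfg, fr))
})

test_that("anchors bind at first occurrences, seq_end strictly after seq_start", {
  cfg <- toy_config()
  fr <- toy_frame(cfg)
  # duplicate seq_end downstream: the first one after seq_start wins
  read <- paste0(toy$ref, "TT", toy$seq_end)
  m <- match_read(read, cfg, fr)
  expect_equal(m$indel_size, 0L)
  # seq_end present only inside/before the seq_start match region is no match
  read2 <- paste0(toy$seq_end, toy$seq_start)
  expect_null(match_read(read2, cfg, fr))
})

test_that("per-sample tallies accumulate counts, bins and QC counters", {
  cfg <- toy_config()
  fr <- toy_frame(cfg)

  r <- tally_sample(rep(toy$ref, 10), cfg, fr, name = "wtonly")
  expect_equal(r$total_reads, 10L)
  expect_equal(r$seq_match_count, 10L)
  expect_equal(r$indel_hist, c("0" = 10L))
  expect_equal(unname(r$test_counts["wt_site"]), 10L)

  seqs <- c(rep(toy$ref, 6), rep(toy$alleles$del45, 4))
  r2 <- tally_sample(seqs, cfg, fr, name = "mix")
  expect_equal(r2$indel_hist[order(as.integer(names(r2$indel_hist)))],
               c("-45" = 4L, "0" = 6L))
  expect_equal(sum(r2$read_bins), r2$seq_match_count)
})

test_that("tallies agree with the brute-force oracle on randomized reads", {
  cfg <- toy_config(test_list = list(wt_site = toy$grna, donorA = toy$blockA,
                                     donorB = toy$blockB))
  fr <- toy_frame(cfg)
  set.seed(42)
  pool <- unlist(toy$alleles, use.names = FALSE)
  seqs <- c(sample(pool, 150, replace = TRUE),
            replicate(50, random_dna(80)))
  r <- tally_sample(seqs, cfg, fr, name = "rand")
  expect_matches_oracle(r, oracle_tally(seqs, cfg, fr))
})

test_that("indel frequencies divide by seq_matches and sum to 100", {
  cfg <- toy_config()
  fr <- toy_frame(cfg)
  seqs <- c(rep(toy$ref, 6), rep(toy$alleles$del45, 4))
  r <- tally_sample(seqs, cfg, fr, name = "s")
  f <- indel_frequencies(r)
  expect_equal(f[["0"]], 60)
  expect_equal(f[["-45"]], 40)
  expect_equal(sum(f), 100)

  r1 <- tally_sample(rep(toy$ref, 10), cfg, fr, name = "s")
  expect_equal(unname(indel_frequencies(r1)), 100)

  empty <- tally_sample(replicate(5, random_dna(40)), cfg, fr, name = "e")
  expect_true(all(is.na(indel_frequencies(empty))))
  expect_true(is.na(total_indel(empty)))
})

test_that("Total_indel is the share of non-wild-type-length seq_matches", {
  cfg <- toy_config()
  fr <- toy_frame(cfg)
  expect_equal(total_indel(tally_sample(rep(toy$ref, 10), cfg, fr, name = "a")), 0)
  expect_equal(total_indel(tally_sample(rep(toy$alleles$ins1, 5), cfg, fr,
                                        name = "b")), 100)
  seqs <- c(rep(toy$ref, 6), rep(toy$alleles$del45, 3), toy$alleles$ins1)
  r <- tally_sample(seqs, cfg, fr, name = "c")
  expect_equal(total_indel(r), 40)
  expect_equal(total_indel(r) + indel_frequencies(r)[["0"]], 100,
               tolerance = 1e-9)
})

test_that("indel ranking sorts by count with |size|-then-deletion tie-breaks", {
  # independent comparator-based sort over the stated key
  oracle_rank <- function(hist, n) {
    sizes <- as.integer(names(hist))
    counts <- as.integer(hist)
    key <- function(i, j) {
      if (counts[i] != counts[j]) return(counts[i] > counts[j])
      if (abs(sizes[i]) != abs(sizes[j])) return(abs(sizes[i]) < abs(sizes[j]))
      sizes[i] < sizes[j]   # deletion (negative) before insertion
    }
    ord <- seq_along(sizes)
    for (a in seq_along(ord)) for (b in seq_along(ord)) {
      if (a < b && key(ord[b], ord[a])) ord[c(a, b)] <- ord[c(b, a)]
    }
    head(sizes[ord], n)
  }
  mk <- function(hist) {
    structure(list(indel_hist = hist, seq_match_count = sum(hist)),
              class = "sample_result")
  }
  cases <- list(
    c("0" = 6L, "-45" = 4L, "1" = 4L),
    c("0" = 10L),
    c("-3" = 5L, "3" = 5L, "0" = 5L, "7" = 2L),
    setNames(rep(3L, 9), as.character(c(-4, -3, -2, -1, 0, 1, 2, 3, 4)))
  )
  for (hist in cases) {
    for (n in c(2L, 8L)) {
      got <- rank_indels(mk(hist), n)
      expect_equal(got$indel_size, oracle_rank(hist, n))
      expect_equal(got$rank, seq_len(nrow(got)))
      expect_true(all(diff(got$reads) <= 0))
    }
  }
  # spec'd tie: +1 outranks -45 at equal counts (smaller magnitude)
  got <- rank_indels(mk(cases[[1]]), 8)
  expect_equal(got$indel_size, c(0L, 1L, -45L))
  # 9 distinct sizes, default 8 ranks: the 9th is dropped
  expect_equal(nrow(rank_indels(mk(cases[[4]]), 8)), 8L)
})

test_that("test sequences are counted independently within seq_matches", {
  cfg <- toy_config(test_list = list(wt_site = toy$grna, donorA = toy$blockA,
                                     absent = "GGGGGGGGGGGG"))
  fr <- toy_frame(cfg)
  seqs <- c(rep(toy$ref, 5), rep(toy$alleles$donorA, 5))
  r <- tally_sample(seqs, cfg, fr, name = "s")
  tf <- test_sequence_frequencies(r)
  expect_equal(tf$test, c("wt_site", "donorA", "absent"))
  expect_equal(tf$reads, c(5L, 5L, 0L))
  expect_equal(tf$percent, c(50, 50, 0))

  # overlapping tests may both hit the same read; percents exceed 100 in sum
  cfg2 <- toy_config(test_list = list(a = substr(toy$grna, 1, 10),
                                      b = substr(toy$grna, 5, 15)))
  r2 <- tally_sample(rep(toy$ref, 4), cfg2, toy_frame(cfg2), name = "s")
  tf2 <- test_sequence_frequencies(r2)
  expect_equal(tf2$percent, c(100, 100))
})

test_that("test-match scope switch widens matching to the raw read", {
  # plant a test sequence in the pad outside the anchored region
  outside <- "TGCATCGGAACT"   # upstream pad of the toy amplicon
  cfg_sm <- toy_config(test_list = list(pad = outside))
  cfg_rr <- toy_config(test_list = list(pad = outside),
                       test_match_scope = "raw_read")
  fr <- toy_frame(cfg_sm)
  r_sm <- tally_sample(rep(toy$ref, 4), cfg_sm, fr, name = "s")
  r_rr <- tally_sample(rep(toy$ref, 4), cfg_rr, fr, name = "s")
  expect_equal(unname(r_sm$test_counts), 0L)
  expect_equal(unname(r_rr$test_counts), 4L)
  expect_matches_oracle(r_rr, oracle_tally(rep(toy$ref, 4), cfg_rr, fr))
})

test_that("QC ratios flag anchor dropout and knockout clones", {
  cfg <- toy_config()
  fr <- toy_frame(cfg)

  # SNP inside seq_start on one of two equal alleles: upstream matched at
  # half the downstream frequency, ratio 1:2 = 0.5
  seqs <- c(rep(toy$ref, 50), rep(toy$alleles$snp_in_start, 50))
  qc <- compute_qc(tally_sample(seqs, cfg, fr, name = "snp"), cfg)
  expect_equal(qc$snp_test, 0.5)

  qc1 <- compute_qc(tally_sample(rep(toy$ref, 100), cfg, fr, name = "wt"), cfg)
  expect_equal(qc1$snp_test, 1)
  expect_equal(qc1$raw_wt_test, 1)
  expect_length(qc1$flags, 0)

  # total knockout clone: first test = gRNA site, absent everywhere -> 0, not NA
  ko <- tally_sample(rep(toy$alleles$del45, 40), cfg, fr, name = "ko")
  qc_ko <- compute_qc(ko, cfg)
  expect_equal(qc_ko$raw_wt_test, 0)
  expect_length(qc_ko$flags, 0)

  # first test present in raw reads but in no seq_match -> undefined, flagged
  raw_only <- paste0(toy$grna, "TTTT")
  qc_un <- compute_qc(tally_sample(rep(raw_only, 5), cfg, fr, name = "u"), cfg)
  expect_true(is.na(qc_un$raw_wt_test))
  expect_match(qc_un$flags, "raw_wt_test undefined", all = FALSE)
})

test_that("conservation invariants hold across simulated scenarios", {
  cfg <- toy_config(test_list = list(wt_site = toy$grna, donorA = toy$blockA))
  fr <- toy_frame(cfg)
  for (seed in 1:5) {
    scn <- scenario(list(allele("WT", toy$ref, 0.5),
                         allele("D45", toy$alleles$del45, 0.2),
                         allele("I1", toy$alleles$ins1, 0.2),
                         allele("DA", toy$alleles$donorA, 0.1)),
                    n_reads = 300, sub_error_rate = 0.01, seed = seed)
    r <- tally_sample(simulate_reads(scn)$sequence, cfg, fr, name = "s")
    expect_equal(sum(r$indel_hist), r$seq_match_count)
    expect_equal(sum(r$read_bins), r$seq_match_count)
    expect_true(all(r$test_counts <= r$seq_match_count))
    expect_gte(r$start_hits, r$seq_match_count)
    expect_gte(r$end_hits, r$seq_match_count)
    if (r$seq_match_count > 0) {
      expect_equal(total_indel(r) + indel_frequencies(r)[["0"]], 100,
                   tolerance = 1e-9)
    }
  }
})

test_that("substitutions never shift indel calls, only membership and bins", {
  cfg <- toy_config()
  fr <- toy_frame(cfg)
  inner_span <- c(23L, 82L)  # ref positions strictly between the anchors
  set.seed(99)
  noiseless <- rep(toy$ref, 400)
  noisy <- vapply(noiseless, function(s) {
    ch <- strsplit(s, "")[[1]]
    hit <- which(runif(length(ch)) < 0.02)
    hit <- hit[hit >= inner_span[1] & hit <= inner_span[2]]
    for (i in hit) ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1)
    paste0(ch, collapse = "")
  }, character(1), USE.NAMES = FALSE)
  r0 <- tally_sample(noiseless, cfg, fr, name = "a")
  r1 <- tally_sample(noisy, cfg, fr, name = "b")
  # inner-only noise: every read still a seq_match, identical indel spectrum
  expect_equal(r1$indel_hist, r0$indel_hist)
  expect_equal(r1$seq_match_count, r0$seq_match_count)
  expect_gt(length(r1$read_bins), length(r0$read_bins))  # bins split, lengths do not
})

test_that("flank noise drops reads from seq_matches without faking indels", {
  cfg <- toy_config()
  fr <- toy_frame(cfg)
  for (seed in 1:3) {
    scn <- make_wt_scenario(toy$ref, 500, error = 0.01, seed = seed)
    r <- tally_sample(simulate_reads(scn)$sequence, cfg, fr, name = "wt")
    expect_lt(r$seq_match_count, r$total_reads)  # some flank hits at 1%/base
    expect_equal(total_indel(r), 0)
    expect_equal(names(r$indel_hist), "0")
  }
})
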