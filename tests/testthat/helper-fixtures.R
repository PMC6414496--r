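# Shared toy amplicon: 12 bp pad | 10 bp upstream anchor | 60 bp inner
# (cut site between inner positions 30/31) | 10 bp downstream anchor | 12 bp pad.
toy <- local({
  up <- "TGCATCGGAACT"
  down <- "ATGGCGTCCTAA"
  seq_start <- "GATTACAGGT"
  seq_end <- "CCTGAACTGT"
  inner <- paste0("ACGTACGTGGTCTTAGCACTGCAAGGTGAC",
                  "TGGAGCTAAGCCAGTATGACGTTCACAGTC")
  ref <- paste0(up, seq_start, inner, seq_end, down)
  loxp <- "ATAACTTCGTATAATGTATGCTATACGAAGTTAT"
  blockA <- "TCCTGTACGGTA"
  blockB <- "GAACGGATTCAC"
  grna <- substr(inner, 21, 40)          # 20 bp spanning the cut site
  cut <- 53                              # 1-based ref position just after the cut
  list(
    ref = ref, seq_start = seq_start, seq_end = seq_end, inner = inner,
    grna = grna, loxp = loxp, loxp_insert = paste0(loxp, "GGATCC"),
    blockA = blockA, blockB = blockB, cut = cut,
    alleles = list(
      wt = ref,
      del45 = ampedit::mutate_allele(ref, 30, 45),
      del15 = ampedit::mutate_allele(ref, 45, 15),
      ins1 = ampedit::mutate_allele(ref, cut, 0, "A"),
      donorA = ampedit::mutate_allele(ref, 48, 12, blockA),
      donorB = ampedit::mutate_allele(ref, 48, 12, blockB),
      subst = ampedit::mutate_allele(ref, 52, 1, "T"),
      loxp_ins = ampedit::mutate_allele(ref, cut, 0, paste0(loxp, "GGATCC")),
      snp_in_start = ampedit::mutate_allele(ref, 17, 1, "G")
    ))
})

toy_config <- function(test_list = list(wt_site = toy$grna), fastq_dir = NULL,
                       ...) {
  ampedit::run_config("toyrun", toy$ref, toy$seq_start, toy$seq_end,
                      test_list = test_list, fastq_dir = fastq_dir, ...)
}

toy_frame <- function(cfg = toy_config()) ampedit::establish_reference(cfg)

# write a plain FASTQ of given sequences to a temp dir; returns the file path
write_seqs_fastq <- function(seqs, path) {
  recs <- data.frame(read_id = sprintf("r%d", seq_along(seqs)),
                     sequence = seqs,
                     quality = strrep("I", nchar(seqs)),
                     stringsAsFactors = FALSE)
  ampedit::write_fastq(recs, path)
}

# random DNA of length n from a given RNG state
random_dna <- function(n) {
  paste0(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
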