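
# Column names that test-sequence names must not collide with.
reserved_column_names <- function(top_indels = 8L) {
  c("Name", "Total_reads", "Seq_matches", "Total_indel",
    "SNP_test", "raw_wt_test",
    paste0("#", seq_len(top_indels), "-Indel"),
    paste0("#", seq_len(top_indels), "-Reads(%)"))
}

check_dna <- function(x, what, allow_empty = FALSE) {
  if (length(x) != 1L || is.na(x)) stop(what, " must be a single string", call. = FALSE)
  if (!allow_empty && !nzchar(x)) stop(what, " must be non-empty", call. = FALSE)
  if (grepl("[^ACGT]", x)) {
    stop(what, " must contain only A/C/G/T bases, got: ", x, call. = FALSE)
  }
  x
}

#' Construct and validate a run configuration
#'
#' Bundles everything one analysis run needs: a run identifier (names the
#' output folder and files), the reference amplicon, the two flanking anchor
#' sequences that bracket the expected cut site, and an ordered named list of
#' test sequences to screen for (donor modifications, base-edit outcomes, the
#' wild-type gRNA site, ...). All sequences are uppercased. Analysis is strand
#' specific: every sequence must be given on the strand of the FASTQ files
#' being analyzed (R1 or R2, not both).
#'
#' @param run_id single string labelling the run; used as output folder and
#'   file name.
#' @param ref_seq reference amplicon sequence (A/C/G/T).
#' @param seq_start upstream flanking anchor, must occur exactly once in
#'   `ref_seq`.
#' @param seq_end downstream flanking anchor, must occur exactly once in
#'   `ref_seq`, entirely downstream of `seq_start`.
#' @param test_list named character vector or named list of test sequences,
#'   in reporting order. Names must be unique and must not equal reserved
#'   report column names. The first entry drives the `raw_wt_test` QC ratio.
#' @param fastq_dir directory of demultiplexed FASTQ files (may be `NULL`
#'   when the configuration is used programmatically on in-memory reads).
#' @param top_indels number of ranked indel sizes reported per sample
#'   (default 8).
#' @param top_reads number of exact-read bins written to the TXT report per
#'   sample (default 10).
#' @param test_match_scope `"seq_match"` (default) counts a test sequence
#'   within the flank-to-flank anchored region of each matched read;
#'   `"raw_read"` counts it anywhere in the full read of each matched read.
#' @return an object of class `run_config`
#' @export
run_config <- function(run_id, ref_seq, seq_start, seq_end, test_list,
                       fastq_dir = NULL, top_indels = 8L, top_reads = 10L,
                       test_match_scope = c("seq_match", "raw_read")) {
  test_match_scope <- match.arg(test_match_scope)
  if (length(run_id) != 1L || is.na(run_id) || !nzchar(run_id)) {
    stop("run_id must be a non-empty string", call. = FALSE)
  }
  ref_seq <- check_dna(toupper(ref_seq), "ref_seq")
  seq_start <- check_dna(toupper(seq_start), "seq_start")
  seq_end <- check_dna(toupper(seq_end), "seq_end")
  tests <- unlist(test_list)
  if (length(tests) == 0L) stop("test_list must contain at least one test sequence", call. = FALSE)
  if (is.null(names(tests)) || any(!nzchar(names(tests)))) {
    stop("every test sequence must be named", call. = FALSE)
  }
  if (anyDuplicated(names(tests))) {
    stop("duplicate test name: ", names(tests)[duplicated(names(tests))][1L],
         call. = FALSE)
  }
  tests <- vapply(tests, function(s) check_dna(toupper(s), "test sequence"),
                  character(1))
  top_indels <- as.integer(top_indels)
  top_reads <- as.integer(top_reads)
  if (is.na(top_indels) || top_indels < 1L) stop("top_indels must be >= 1", call. = FALSE)
  if (is.na(top_reads) || top_reads < 1L) stop("top_reads must be >= 1", call. = FALSE)
  clash <- intersect(names(tests), reserved_column_names(top_indels))
  if (length(clash)) {
    stop("test name collides with a reserved report column: ", clash[1L],
         call. = FALSE)
  }
  structure(list(run_id = run_id, ref_seq = ref_seq, seq_start = seq_start,
                 seq_end = seq_end, test_list = tests, fastq_dir = fastq_dir,
                 top_indels = top_indels, top_reads = top_reads,
                 test_match_scope = test_match_scope),
            class = "run_config")
}

#' @export
print.run_config <- function(x, ...) {
  cat("Amplicon run configuration '", x$run_id, "'\n", sep = "")
  cat("  ref_seq:   ", nchar(x$ref_seq), " bp\n", sep = "")
  cat("  seq_start: ", x$seq_start, "\n", sep = "")
  cat("  seq_end:   ", x$seq_end, "\n", sep = "")
  cat("  tests:     ", paste(names(x$test_list), collapse = ", "), "\n", sep = "")
  cat("  fastq_dir: ", if (is.null(x$fastq_dir)) "<none>" else x$fastq_dir,
      "\n", sep = "")
  cat("  top_indels: ", x$top_indels, ", top_reads: ", x$top_reads,
      ", test scope: ", x$test_match_scope, "\n", sep = "")
  invisible(x)
}

#' Read and validate a run configuration from a YAML file
#'
#' The file externalizes the run variables: keys `id`, `ref_seq`,
#' `seq_start`, `seq_end`, `test_list` (a mapping of name to sequence, order
#' preserved), `fastq_dir`, and optional `top_indels`, `top_reads`,
#' `test_match_scope`, `out_dir`. The reference frame is resolved immediately
#' so anchor errors (absent or ambiguous flank) surface before any FASTQ
#' file is touched.
#'
#' @param config_path path to the YAML configuration
#' @param overrides named list overriding `out_dir`, `top_indels`,
#'   `top_reads` or `test_match_scope`
#' @return a validated `run_config`; the output directory (default `"."`) is
#'   attached as attribute `out_dir`.
#' @export
validate_config <- function(config_path, overrides = list()) {
  if (!file.exists(config_path)) {
    stop("config file not found: ", config_path, call. = FALSE)
  }
  raw <- yaml::read_yaml(config_path)
  required <- c("id", "ref_seq", "seq_start", "seq_end", "test_list")
  missing <- setdiff(required, names(raw))
  if (length(missing)) {
    stop("config is missing required field(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  get_opt <- function(key, default) {
    if (!is.null(overrides[[key]])) overrides[[key]] else
      if (!is.null(raw[[key]])) raw[[key]] else default
  }
  cfg <- run_config(
    run_id = raw$id,
    ref_seq = raw$ref_seq,
    seq_start = raw$seq_start,
    seq_end = raw$seq_end,
    test_list = raw$test_list,
    fastq_dir = if (!is.null(raw$fastq_dir)) raw$fastq_dir else NULL,
    top_indels = get_opt("top_indels", 8L),
    top_reads = get_opt("top_reads", 10L),
    test_match_scope = get_opt("test_match_scope", "seq_match")
  )
  establish_reference(cfg)  # dry-run: frame errors surface now
  attr(cfg, "out_dir") <- get_opt("out_dir", ".")
  cfg
}
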