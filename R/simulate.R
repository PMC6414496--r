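#' Define an allele of an amplicon
#'
#' An allele is a full amplicon sequence present in a sample at a known
#' proportion — wild type, an NHEJ indel allele, an HDR/knock-in allele, a
#' SNP-bearing allele, and so on.
#'
#' @param name allele label (becomes part of simulated read ids)
#' @param sequence full amplicon sequence for this allele (A/C/G/T)
#' @param proportion fraction of reads drawn from this allele, in \[0, 1\]
#' @return list of class `allele`
#' @export
allele <- function(name, sequence, proportion) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  sequence <- check_dna(toupper(sequence), paste0("allele '", name, "' sequence"))
  stopifnot(is.numeric(proportion), proportion >= 0, proportion <= 1)
  structure(list(name = name, sequence = sequence, proportion = proportion),
            class = "allele")
}

#' Define a simulation scenario
#'
#' A scenario is a sample's ground truth: an allele mixture whose proportions
#' sum to 1, a read count, a per-base substitution error rate emulating
#' Illumina-type sequencing noise (substitutions dominate; indel errors are
#' roughly two orders of magnitude rarer and are off by default), and a seed
#' making the generated reads fully reproducible.
#'
#' @param alleles list of [allele()] objects; proportions must sum to 1
#'   (tolerance 1e-9)
#' @param n_reads number of reads to generate (>= 1)
#' @param sub_error_rate per-base substitution probability in \[0, 1)
#' @param seed integer RNG seed
#' @param sample_name sample label (FASTQ stem and read-id prefix)
#' @param indel_error_rate optional per-base probability of a 1-bp
#'   sequencing indel error (half deletions, half insertions); default 0
#' @return list of class `scenario`
#' @export
scenario <- function(alleles, n_reads, sub_error_rate = 0, seed = 1L,
                     sample_name = "sample", indel_error_rate = 0) {
  stopifnot(length(alleles) >= 1L,
            all(vapply(alleles, inherits, logical(1), "allele")))
  p <- vapply(alleles, `[[`, numeric(1), "proportion")
  if (abs(sum(p) - 1) > 1e-9) {
    stop("allele proportions must sum to 1, got ", sum(p), call. = FALSE)
  }
  n_reads <- as.integer(n_reads)
  stopifnot(n_reads >= 1L, sub_error_rate >= 0, sub_error_rate < 1,
            indel_error_rate >= 0, indel_error_rate < 1)
  structure(list(alleles = alleles, n_reads = n_reads,
                 sub_error_rate = sub_error_rate,
                 indel_error_rate = indel_error_rate,
                 seed = as.integer(seed), sample_name = sample_name),
            class = "scenario")
}

#' Wild-type-only scenario (negative-control emulation)
#'
#' @param ref_seq the amplicon sequence
#' @param n_reads number of reads
#' @param error per-base substitution rate
#' @param seed RNG seed
#' @param sample_name sample label
#' @return a [scenario()] with a single allele at proportion 1
#' @export
make_wt_scenario <- function(ref_seq, n_reads, error = 0, seed = 1L,
                             sample_name = "wt") {
  scenario(list(allele("WT", ref_seq, 1)), n_reads,
           sub_error_rate = error, seed = seed, sample_name = sample_name)
}

#' Apply an edit to a reference amplicon
#'
#' Constructs an edited allele sequence: `delete_len` bases are removed
#' starting at 1-based `position`, and `insert_seq` is inserted there. Use a
#' pure deletion for NHEJ deletion alleles, a pure insertion for knock-ins
#' (e.g. a 34-bp loxP site plus a 6-bp restriction site), or both for
#' replacement/HDR block edits.
#'
#' @param ref_seq reference amplicon
#' @param position 1-based position of the edit
#' @param delete_len number of bases removed at `position` (default 0)
#' @param insert_seq sequence inserted at `position` (default none)
#' @return the edited sequence
#' @examples
#' mutate_allele("AAACCCGGG", 4, delete_len = 3)            # "AAAGGG"
#' mutate_allele("AAACCCGGG", 4, insert_seq = "TT")         # "AAATTCCCGGG"
#' @export
mutate_allele <- function(ref_seq, position, delete_len = 0L, insert_seq = "") {
  ref_seq <- toupper(ref_seq)
  position <- as.integer(position)
  delete_len <- as.integer(delete_len)
  stopifnot(position >= 1L, delete_len >= 0L)
  if (position - 1L + delete_len > nchar(ref_seq)) {
    stop("edit extends past the end of ref_seq", call. = FALSE)
  }
  if (nzchar(insert_seq)) {
    insert_seq <- check_dna(toupper(insert_seq), "insert_seq")
  }
  paste0(substr(ref_seq, 1L, position - 1L), insert_seq,
         substr(ref_seq, position + delete_len, nchar(ref_seq)))
}

#' Largest-remainder allocation of reads to alleles
#'
#' Deterministically converts proportions into integer counts summing to
#' `n`: each allele gets `floor(p * n)` reads, and the remaining reads go to
#' the largest fractional remainders (ties broken by allele order). Realized
#' counts are therefore exact, which is what makes zero-noise simulations
#' recover reported frequencies exactly.
#'
#' @param proportions numeric vector summing to 1
#' @param n total reads
#' @return integer vector of counts summing to `n`
#' @export
allocate_counts <- function(proportions, n) {
  exact <- proportions * n
  base <- floor(exact)
  left <- as.integer(round(n - sum(base)))
  counts <- as.integer(base)
  if (left > 0L) {
    frac <- exact - base
    extra <- order(-frac, seq_along(frac))[seq_len(left)]
    counts[extra] <- counts[extra] + 1L
  }
  counts
}

# substitute each selected base with one of the three other bases
.base_alternatives <- matrix(
  c("C", "G", "T",   # A ->
    "A", "G", "T",   # C ->
    "A", "C", "T",   # G ->
    "A", "C", "G"),  # T ->
  nrow = 4L, byrow = TRUE,
  dimnames = list(c("A", "C", "G", "T"), NULL))

apply_substitutions <- function(chars, rate) {
  if (rate <= 0) return(chars)
  hit <- which(stats::runif(length(chars)) < rate)
  if (length(hit)) {
    pick <- sample.int(3L, length(hit), replace = TRUE)
    chars[hit] <- .base_alternatives[cbind(match(chars[hit],
                                                 rownames(.base_alternatives)),
                                           pick)]
  }
  chars
}

#' Generate the reads of a scenario
#'
#' Produces exactly `n_reads` records: allele assignment by deterministic
#' largest-remainder allocation, then seeded per-base substitution noise
#' (and, when enabled, rare 1-bp sequencing indel errors). Quality strings
#' are a constant high-quality character — the analysis is quality-agnostic.
#' The caller's RNG state is preserved; identical scenarios yield identical
#' reads.
#'
#' @param scn a [scenario()]
#' @return data.frame of FASTQ records (`read_id`, `sequence`, `quality`)
#' @export
simulate_reads <- function(scn) {
  stopifnot(inherits(scn, "scenario"))
  old_seed <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(scn$seed)

  p <- vapply(scn$alleles, `[[`, numeric(1), "proportion")
  counts <- allocate_counts(p, scn$n_reads)
  seqs <- rep(vapply(scn$alleles, `[[`, character(1), "sequence"), counts)
  origin <- rep(vapply(scn$alleles, `[[`, character(1), "name"), counts)

  if (scn$sub_error_rate > 0 || scn$indel_error_rate > 0) {
    chars_list <- strsplit(seqs, "", fixed = TRUE)
    lens <- lengths(chars_list)
    chars <- unlist(chars_list, use.names = FALSE)
    chars <- apply_substitutions(chars, scn$sub_error_rate)
    read_of <- rep.int(seq_along(seqs), lens)
    if (scn$indel_error_rate > 0) {
      keep <- stats::runif(length(chars)) >= scn$indel_error_rate / 2
      ins_hit <- stats::runif(length(chars)) < scn$indel_error_rate / 2
      ins <- character(length(chars))
      if (any(ins_hit)) {
        ins[ins_hit] <- sample(rownames(.base_alternatives), sum(ins_hit),
                               replace = TRUE)
      }
      chars <- paste0(ifelse(keep, chars, ""), ins)
    }
    seqs <- vapply(split(chars, read_of), paste, character(1), collapse = "")
    seqs <- unname(seqs[as.character(seq_along(lens))])
  }

  data.frame(
    read_id = sprintf("%s:%s:%d", scn$sample_name, origin, seq_along(seqs)),
    sequence = seqs,
    quality = strrep("I", nchar(seqs)),
    stringsAsFactors = FALSE)
}

#' Render a scenario to a FASTQ file
#'
#' Writes [simulate_reads()] output as standard 4-line FASTQ (gzipped when
#' `path` ends in `.gz`). Byte-identical for identical scenarios.
#'
#' @param scn a [scenario()]
#' @param path output path; default `<sample_name>.fastq` under `dir`
#' @param dir directory used when `path` is `NULL`
#' @return the written path, invisibly
#' @export
render_fastq <- function(scn, path = NULL, dir = ".") {
  if (is.null(path)) path <- file.path(dir, paste0(scn$sample_name, ".fastq"))
  write_fastq(simulate_reads(scn), path)
}
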