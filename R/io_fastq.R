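#' Natural-order sorting of sample names
#'
#' Orders strings so that embedded integers compare numerically
#' (`a2 < a10`), matching how plate/well filenames are expected to sort.
#' Non-digit runs compare bytewise (C locale) for platform-independent,
#' deterministic order.
#'
#' @param x character vector
#' @return integer permutation that sorts `x` into natural order
#' @keywords internal
natural_order <- function(x) {
  if (length(x) == 0L) return(integer(0))
  toks <- regmatches(x, gregexpr("[0-9]+|[^0-9]+", x))
  # pad every digit run to fixed width so bytewise order == numeric order
  keys <- vapply(toks, function(tt) {
    digit <- grepl("^[0-9]", tt)
    tt[digit] <- formatC(sub("^0+(?=[0-9])", "", tt[digit], perl = TRUE),
                         width = 24L, flag = "0")
    paste0(tt, collapse = "")
  }, character(1))
  order(keys, x, method = "radix")
}

#' Strip FASTQ extensions from a filename
#' @keywords internal
strip_fastq_ext <- function(filename) {
  sub("\\.(fastq|fq)(\\.gz)?$", "", filename)
}

#' Discover FASTQ sample files in a directory
#'
#' Lists every `*.fastq`, `*.fq`, `*.fastq.gz` and `*.fq.gz` file directly in
#' `directory` (non-recursive), one file per sample/well, in natural sort
#' order of the extension-stripped name. The stripped name becomes the
#' sample's `Name` in all reports and must be unique within the run.
#'
#' @param directory path to a readable directory of demultiplexed FASTQ files
#' @return data.frame with columns `name` (stripped stem) and `path`,
#'   ordered naturally by `name`; zero rows if the directory holds no FASTQ.
#' @examples
#' d <- tempfile(); dir.create(d)
#' file.create(file.path(d, c("a10.fastq", "a2.fastq", "a1.fastq")))
#' discover_samples(d)$name   # "a1" "a2" "a10"
#' @export
discover_samples <- function(directory) {
  if (length(directory) != 1L || !dir.exists(directory)) {
    stop("fastq directory does not exist or is not a directory: ",
         directory, call. = FALSE)
  }
  if (file.access(directory, mode = 4L) != 0L) {
    stop("fastq directory is not readable: ", directory, call. = FALSE)
  }
  files <- list.files(directory,
                      pattern = "\\.(fastq|fq)(\\.gz)?$",
                      full.names = FALSE, recursive = FALSE)
  names_ <- strip_fastq_ext(files)
  if (anyDuplicated(names_)) {
    dup <- names_[duplicated(names_)][1L]
    both <- files[names_ == dup]
    stop("duplicate sample stem '", dup, "' from files: ",
         paste(both, collapse = ", "), call. = FALSE)
  }
  ord <- natural_order(names_)
  out <- data.frame(name = names_[ord],
                    path = file.path(directory, files[ord]),
                    stringsAsFactors = FALSE)
  class(out) <- c("sample_files", "data.frame")
  out
}

#' Read all records of a FASTQ file
#'
#' Parses a 4-line-per-record FASTQ file (plain, or gzip when the filename
#' ends in `.gz`). Sequences are uppercased; quality strings are retained but
#' never used downstream (classification is exact-match, quality-agnostic).
#'
#' @param path path to a FASTQ file
#' @return data.frame with columns `read_id`, `sequence`, `quality`, in file
#'   order.
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop("FASTQ file not found: ", path, call. = FALSE)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  n <- length(lines)
  if (n %% 4L != 0L) {
    stop("truncated FASTQ record at record ", n %/% 4L + 1L, " in ", path,
         call. = FALSE)
  }
  if (n == 0L) {
    return(data.frame(read_id = character(0), sequence = character(0),
                      quality = character(0), stringsAsFactors = FALSE))
  }
  idx <- seq(1L, n, by = 4L)
  header <- lines[idx]
  seqs <- toupper(lines[idx + 1L])
  plus <- lines[idx + 2L]
  qual <- lines[idx + 3L]
  bad_hdr <- which(!startsWith(header, "@"))
  if (length(bad_hdr)) {
    stop("malformed FASTQ header at record ", bad_hdr[1L], " in ", path,
         call. = FALSE)
  }
  bad_plus <- which(!startsWith(plus, "+"))
  if (length(bad_plus)) {
    stop("missing '+' separator at record ", bad_plus[1L], " in ", path,
         call. = FALSE)
  }
  bad_len <- which(nchar(qual) != nchar(seqs))
  if (length(bad_len)) {
    stop("quality/sequence length mismatch at record ", bad_len[1L], " in ",
         path, call. = FALSE)
  }
  bad_alpha <- which(grepl("[^ACGTN]", seqs))
  if (length(bad_alpha)) {
    stop("non-ACGTN base in sequence at record ", bad_alpha[1L], " in ", path,
         call. = FALSE)
  }
  data.frame(read_id = sub("^@", "", header), sequence = seqs,
             quality = qual, stringsAsFactors = FALSE)
}

#' Write FASTQ records
#'
#' Writes standard 4-line FASTQ; gzip-compressed when `path` ends in `.gz`.
#'
#' @param records data.frame with columns `read_id`, `sequence`, `quality`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_fastq <- function(records, path) {
  stopifnot(all(c("read_id", "sequence", "quality") %in% names(records)))
  lines <- as.vector(rbind(paste0("@", records$read_id),
                           records$sequence,
                           "+",
                           records$quality))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}
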