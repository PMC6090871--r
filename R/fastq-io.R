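#' Read a FASTQ file into a tidy read table
#'
#' Reads single-end small RNA reads (plain or gzip FASTQ) into a tibble with
#' one row per read. Sequences are uppercased and any `U` is mapped to `T`,
#' so downstream matching is always in DNA space.
#'
#' @param path Path to a FASTQ file (`.fastq`, `.fq`, optionally `.gz`).
#'
#' @return A tibble with columns `read_id`, `sequence`, `quality`.
#' @examples
#' fq <- tempfile(fileext = ".fastq")
#' writeLines(c("@r1", "ACGT", "+", "IIII"), fq)
#' read_fastq(fq)
#' @export
read_fastq <- function(path) {
  stopifnot(is.character(path), length(path) == 1L)
  if (!file.exists(path)) abort(paste0("FASTQ file not found: ", path))
  x <- tryCatch(
    Biostrings::readBStringSet(path, format = "fastq", with.qualities = TRUE),
    error = function(e) {
      abort(paste0("malformed FASTQ in '", path, "': ", conditionMessage(e)))
    }
  )
  reads <- tibble(
    read_id = unname(names(x)) %||% paste0("read", seq_along(x)),
    sequence = unname(normalize_seq(as.character(x))),
    quality = unname(as.character(S4Vectors::mcols(x)$qualities))
  )
  validate_reads(reads)
  reads
}

#' Write a tidy read table to FASTQ
#'
#' @param reads A tibble with columns `read_id`, `sequence`, `quality`.
#' @param path Output path; a `.gz` suffix triggers gzip compression.
#'
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  validate_reads(reads)
  x <- Biostrings::DNAStringSet(reads$sequence)
  names(x) <- reads$read_id
  Biostrings::writeXStringSet(
    x, path,
    format = "fastq",
    qualities = Biostrings::BStringSet(reads$quality),
    compress = grepl("\\.gz$", path)
  )
  invisible(path)
}

# uppercase and RNA->DNA; keeps IUPAC letters as-is otherwise
normalize_seq <- function(x) {
  chartr("U", "T", toupper(x))
}

validate_reads <- function(reads, require_nonempty = TRUE) {
  need <- c("read_id", "sequence", "quality")
  if (!all(need %in% names(reads))) {
    abort(paste0(
      "read table must have columns ",
      paste(need, collapse = ", ")
    ))
  }
  bad <- which(nchar(reads$sequence) != nchar(reads$quality))
  if (length(bad)) {
    abort(paste0(
      "malformed read record at index ", bad[1L],
      ": sequence and quality lengths differ"
    ))
  }
  if (require_nonempty) {
    empty <- which(!nzchar(reads$sequence))
    if (length(empty)) {
      abort(paste0("malformed read record at index ", empty[1L], ": empty sequence"))
    }
  }
  invisible(reads)
}
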