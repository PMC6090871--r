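#' Illumina Universal Adapter used by NEBNext small RNA libraries
#'
#' Default 3' adapter clipped from raw small RNA reads.
#' @export
srna_adapter <- "AGATCGGAAGAGCACACGTCTGAACTCCAGTCAC"

#' Clip the 3' adapter, keeping only clipped reads
#'
#' Removes everything from the first occurrence of the adapter onwards.
#' Small RNA inserts are shorter than the read, so a read without any
#' adapter signal is most likely not a genuine small RNA; by default such
#' unclipped reads are discarded (`require_adapter = TRUE`), reproducing
#' the "keep clipped sequences, discard non-clipped" behaviour of classic
#' FASTX-style clippers. When the full adapter does not fit before the end
#' of the read, an adapter *prefix* of at least `min_prefix` nucleotides
#' flush with the 3' terminus also counts as a match.
#'
#' @param reads Tibble of reads (`read_id`, `sequence`, `quality`), e.g.
#'   from [read_fastq()].
#' @param adapter Adapter sequence (ACGT only, length >= 8). Defaults to
#'   [srna_adapter].
#' @param min_len Minimum clipped-insert length; shorter inserts are
#'   discarded (default 16, the shortest credible annotated small RNA).
#' @param require_adapter Discard reads without any adapter match
#'   (default `TRUE`). When `FALSE`, unmatched reads pass through unclipped.
#' @param min_prefix Minimum length of a 3'-terminal adapter prefix that
#'   counts as a match (default 8).
#'
#' @return A tibble of clipped reads with a `"clip_stats"` attribute;
#'   retrieve it with [clip_stats()]. Every output sequence is a prefix of
#'   its input sequence.
#' @examples
#' reads <- tibble::tibble(
#'   read_id = "r1",
#'   sequence = paste0("ACGTACGTACGTACGTACGT", srna_adapter, "TT"),
#'   quality = strrep("I", 20 + nchar(srna_adapter) + 2)
#' )
#' clipped <- clip_adapter(reads)
#' clipped$sequence
#' clip_stats(clipped)
#' @export
clip_adapter <- function(reads, adapter = srna_adapter, min_len = 16L,
                         require_adapter = TRUE, min_prefix = 8L) {
  validate_reads(reads)
  adapter <- normalize_seq(adapter)
  if (nchar(adapter) < 8L || grepl("[^ACGT]", adapter)) {
    abort("adapter must be >= 8 nt of ACGT only")
  }
  if (min_len < 1L) abort("min_len must be >= 1")

  n <- nrow(reads)
  seqs <- reads$sequence
  # first full-adapter occurrence; 0-based clip point = pos - 1
  pos <- regexpr(adapter, seqs, fixed = TRUE)
  insert_len <- ifelse(pos > 0L, as.integer(pos) - 1L, NA_integer_)

  # fall back: longest adapter prefix (>= min_prefix) flush with the 3' end
  todo <- which(is.na(insert_len))
  if (length(todo) && nchar(adapter) - 1L >= min_prefix) {
    for (k in seq(nchar(adapter) - 1L, min_prefix)) {
      if (!length(todo)) break
      hit <- endsWith(seqs[todo], substr(adapter, 1L, k))
      if (any(hit)) {
        idx <- todo[hit]
        insert_len[idx] <- nchar(seqs[idx]) - k
        todo <- todo[!hit]
      }
    }
  }

  matched <- !is.na(insert_len)
  keep_len <- insert_len
  if (!require_adapter) keep_len[!matched] <- nchar(seqs[!matched])

  status <- rep("kept", n)
  status[!matched & require_adapter] <- "discarded_unclipped"
  short <- !is.na(keep_len) & keep_len < min_len
  status[short & status == "kept"] <- "discarded_short"

  kept <- status == "kept"
  out <- tibble(
    read_id = reads$read_id[kept],
    sequence = substr(seqs[kept], 1L, keep_len[kept]),
    quality = substr(reads$quality[kept], 1L, keep_len[kept])
  )
  stats <- tibble(
    input = n,
    kept = sum(kept),
    discarded_unclipped = sum(status == "discarded_unclipped"),
    discarded_short = sum(status == "discarded_short")
  )
  attr(out, "clip_stats") <- stats
  out
}

#' Remove a single leading ambiguous base
#'
#' The Illumina HiSeq 4000 can emit an `N` at the first cycle; this strips
#' exactly one leading `N` (sequence and quality) from each affected read.
#' Internal `N`s are untouched. Reads that become empty are dropped and
#' counted.
#'
#' @param reads Tibble of reads (`read_id`, `sequence`, `quality`).
#' @return A tibble of reads with a `"trim_stats"` attribute
#'   (see [trim_stats()]) reporting the fraction of reads affected.
#' @examples
#' reads <- tibble::tibble(
#'   read_id = c("a", "b"),
#'   sequence = c("NACGT", "ANCGT"),
#'   quality = c("IIIII", "IIIII")
#' )
#' trim_leading_n(reads)$sequence
#' @export
trim_leading_n <- function(reads) {
  validate_reads(reads)
  affected <- startsWith(reads$sequence, "N")
  out <- reads
  out$sequence[affected] <- substring(out$sequence[affected], 2L)
  out$quality[affected] <- substring(out$quality[affected], 2L)
  empty <- !nzchar(out$sequence)
  if (any(empty)) out <- out[!empty, , drop = FALSE]
  stats <- tibble(
    input = nrow(reads),
    affected = sum(affected),
    fraction_affected = if (nrow(reads)) sum(affected) / nrow(reads) else 0,
    dropped_empty = sum(empty)
  )
  attr(out, "trim_stats") <- stats
  out
}

#' Accessors for preprocessing statistics
#'
#' @param x A read tibble returned by [clip_adapter()] or [trim_leading_n()].
#' @return A one-row tibble of counts.
#' @export
clip_stats <- function(x) attr(x, "clip_stats")

#' @rdname clip_stats
#' @export
trim_stats <- function(x) attr(x, "trim_stats")
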