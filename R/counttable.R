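#' Collapse reads to unique sequences with occurrence counts
#'
#' Replaces identical reads by one record carrying the sequence and the
#' number of times it was seen in the sample.
#'
#' @param reads Tibble of preprocessed reads (`sequence` column required).
#' @param sample_id Single string identifying the library.
#'
#' @return A tibble with columns `sample_id`, `sequence`, `count`, ordered
#'   by descending count (ties broken by sequence). The sum of `count`
#'   equals the number of input reads.
#' @examples
#' reads <- tibble::tibble(
#'   read_id = c("a", "b", "c"),
#'   sequence = c("ACGT", "ACGT", "TTTT"),
#'   quality = c("IIII", "IIII", "IIII")
#' )
#' collapse_reads(reads, "s1")
#' @export
collapse_reads <- function(reads, sample_id) {
  stopifnot(is.character(sample_id), length(sample_id) == 1L)
  if (!"sequence" %in% names(reads)) abort("reads must have a 'sequence' column")
  if (nrow(reads) == 0L) {
    warn(paste0("no reads for sample '", sample_id, "'; empty collapsed sample"))
    return(tibble(sample_id = character(), sequence = character(), count = integer()))
  }
  reads |>
    count(sequence = .data$sequence, name = "count") |>
    mutate(sample_id = sample_id, count = as.integer(.data$count)) |>
    arrange(dplyr::desc(.data$count), .data$sequence) |>
    select("sample_id", "sequence", "count")
}

#' Join collapsed samples into one unique-sequence count table
#'
#' Joins per-sample collapsed counts by the sequence string into a wide
#' table: one row per unique sequence, one integer column per sample,
#' zeros where a sequence was not seen. Per-sample library sizes (column
#' sums of the unfiltered table) are stored in the `"library_sizes"`
#' attribute and are deliberately preserved, not recomputed, by
#' [filter_table()], so that CPM always refers to the original sequencing
#' depth.
#'
#' @param samples Either a list of collapsed-sample tibbles or a single
#'   long tibble with columns `sample_id`, `sequence`, `count`.
#'
#' @return A tibble with first column `sequence` followed by one column
#'   per sample, rows ordered by descending total count (ties by
#'   sequence). Attribute `"library_sizes"`: named integer vector.
#' @examples
#' a <- tibble::tibble(sample_id = "A", sequence = "ACGT", count = 2L)
#' b <- tibble::tibble(sample_id = "B", sequence = "TTTT", count = 3L)
#' join_samples(list(a, b))
#' @export
join_samples <- function(samples) {
  long <- if (is.data.frame(samples)) samples else bind_rows(samples)
  need <- c("sample_id", "sequence", "count")
  if (!all(need %in% names(long))) {
    abort("collapsed samples need columns sample_id, sequence, count")
  }
  ids <- unique(long$sample_id)
  if (!is.data.frame(samples)) {
    per <- unlist(lapply(samples, function(s) unique(s$sample_id)))
    if (anyDuplicated(per)) {
      abort(paste0("duplicate sample_id: ", per[duplicated(per)][1]))
    }
  }
  if (anyDuplicated(long[c("sample_id", "sequence")])) {
    abort("duplicate (sample_id, sequence) pairs; collapse each sample first")
  }
  wide <- long |>
    mutate(sample_id = factor(.data$sample_id, levels = ids)) |>
    tidyr::pivot_wider(
      names_from = "sample_id", values_from = "count",
      values_fill = 0L, names_expand = TRUE
    )
  tot <- rowSums(wide[ids])
  wide <- wide[order(-tot, wide$sequence), , drop = FALSE]
  lib <- vapply(wide[ids], sum, numeric(1))
  attr(wide, "library_sizes") <- setNames(as.integer(lib), ids)
  wide
}

#' Library sizes attached to a count table
#'
#' @param table A count table from [join_samples()] (or [read_count_table()]).
#' @return Named integer vector of per-sample library sizes.
#' @export
library_sizes <- function(table) {
  ls <- attr(table, "library_sizes")
  if (is.null(ls)) {
    ids <- setdiff(names(table), "sequence")
    ls <- setNames(as.integer(vapply(table[ids], sum, numeric(1))), ids)
  }
  ls
}

#' Counts per million
#'
#' `cpm()` scales a read count by its library size times one million.
#' `cutoff_from_reads()` is the inverse convenience used to pick a CPM
#' cutoff corresponding to an average per-library read count (e.g. an
#' average of 20 reads in a 7.58 M-read library is 2.64 CPM).
#'
#' @param count Read count(s).
#' @param library_size Positive library size(s) (total post-preprocessing
#'   reads in the sample).
#' @return Numeric CPM value(s).
#' @examples
#' cpm(20, 7575758)
#' cutoff_from_reads(20, 7575758)
#' @export
cpm <- function(count, library_size) {
  if (any(library_size <= 0)) abort("library_size must be > 0")
  count / library_size * 1e6
}

#' @rdname cpm
#' @param target_reads Average per-library read count the cutoff should
#'   correspond to.
#' @param mean_library_size Mean library size across samples.
#' @export
cutoff_from_reads <- function(target_reads, mean_library_size) {
  if (any(target_reads < 0)) abort("target_reads must be >= 0")
  if (any(mean_library_size <= 0)) abort("mean_library_size must be > 0")
  target_reads / mean_library_size * 1e6
}

#' Filter a count table on CPM evidence
#'
#' Retains a sequence iff its CPM is at least `cutoff_cpm` (inclusive) in
#' at least `min_samples` samples. CPM is always computed against the
#' library sizes of the *unfiltered* table (frozen in the
#' `"library_sizes"` attribute), so repeated filtering never changes the
#' meaning of the rule. Alternatively pass `target_reads` to derive the
#' cutoff from the mean library size via [cutoff_from_reads()].
#'
#' @param table Count table from [join_samples()].
#' @param cutoff_cpm Positive CPM cutoff (e.g. 2.64).
#' @param min_samples Minimum number of samples meeting the cutoff
#'   (e.g. 5 out of 36 libraries).
#' @param target_reads Optional; if given, overrides `cutoff_cpm` with
#'   `cutoff_from_reads(target_reads, mean(library_sizes))`.
#'
#' @return The filtered table (same columns, same library-size attribute)
#'   with a `"filter_stats"` attribute; see [filter_stats()].
#' @export
filter_table <- function(table, cutoff_cpm = NULL, min_samples = 1L,
                         target_reads = NULL) {
  lib <- library_sizes(table)
  ids <- names(lib)
  if (min_samples > length(ids)) {
    abort("min_samples exceeds the number of samples")
  }
  if (!is.null(target_reads)) {
    cutoff_cpm <- cutoff_from_reads(target_reads, mean(lib))
  }
  if (is.null(cutoff_cpm) || cutoff_cpm < 0) {
    abort("supply a non-negative cutoff_cpm (or target_reads)")
  }
  mat <- as.matrix(table[ids])
  cpm_mat <- sweep(mat, 2L, lib, "/") * 1e6
  keep <- rowSums(cpm_mat >= cutoff_cpm) >= min_samples
  out <- table[keep, , drop = FALSE]
  attr(out, "library_sizes") <- lib
  attr(out, "filter_stats") <- tibble(
    cutoff_cpm = cutoff_cpm,
    min_samples = as.integer(min_samples),
    rows_before = nrow(table),
    rows_after = sum(keep)
  )
  out
}

#' @rdname filter_table
#' @export
filter_stats <- function(table) attr(table, "filter_stats")

#' Read or write a count table as tab-separated text
#'
#' The on-disk format is a header row of sample ids with a first column
#' named `sequence`. A table read back is assumed unfiltered: its library
#' sizes are taken as the column sums.
#'
#' @param table Count table.
#' @param path File path.
#' @return `write_count_table()` returns `path` invisibly;
#'   `read_count_table()` returns a count-table tibble.
#' @export
write_count_table <- function(table, path) {
  readr::write_tsv(table, path)
  invisible(path)
}

#' @rdname write_count_table
#' @export
read_count_table <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE)
  if (names(tab)[1] != "sequence") abort("first column must be 'sequence'")
  ids <- setdiff(names(tab), "sequence")
  tab <- mutate(tab, across(all_of(ids), as.integer))
  attr(tab, "library_sizes") <-
    setNames(as.integer(vapply(tab[ids], sum, numeric(1))), ids)
  tab
}

#' Export an edgeR-ready integer count matrix
#'
#' Returns the raw integer matrix (sequences as rownames, samples as
#' columns) with no normalization applied, suitable for
#' `edgeR::DGEList()`. Differential-expression statistics themselves are
#' edgeR's job, not this package's.
#'
#' @param table Count table from [join_samples()] or [aggregate_to_mirna()].
#' @param id_col Name of the identifier column (default `"sequence"`).
#' @return Integer matrix.
#' @export
as_edger_counts <- function(table, id_col = "sequence") {
  ids <- setdiff(names(table), id_col)
  ids <- ids[vapply(table[ids], is.numeric, TRUE)]
  m <- as.matrix(table[ids])
  storage.mode(m) <- "integer"
  rownames(m) <- table[[id_col]]
  m
}
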