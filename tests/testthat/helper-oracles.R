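# Independent oracles, deliberately naive and free of Biostrings.

revcomp_chr <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
  }, "", USE.NAMES = FALSE)
}

# naive O(n*m) substring scan: slide the query over every reference position
naive_scan_one <- function(q, subject) {
  L <- nchar(q)
  S <- nchar(subject)
  if (L > S || L == 0L) return(integer())
  hits <- integer()
  for (p in 0:(S - L)) {
    if (substr(subject, p + 1L, p + L) == q) hits <- c(hits, p)
  }
  hits
}

naive_search <- function(queries, refs,
                         minus_strand_classes = c("pirna_cluster", "mrna")) {
  out <- list()
  for (q in unique(queries)) {
    if (grepl("N", q, fixed = TRUE) || !nzchar(q)) next
    for (i in seq_len(nrow(refs))) {
      for (p in naive_scan_one(q, refs$sequence[i])) {
        out[[length(out) + 1L]] <- data.frame(
          query_seq = q, record_id = refs$record_id[i],
          q_start = 0L, q_end = nchar(q),
          s_start = p, s_end = p + nchar(q),
          strand = "+", mismatches = 0L, gaps = 0L
        )
      }
      if (refs$rna_class[i] %in% minus_strand_classes) {
        for (p in naive_scan_one(revcomp_chr(q), refs$sequence[i])) {
          out[[length(out) + 1L]] <- data.frame(
            query_seq = q, record_id = refs$record_id[i],
            q_start = 0L, q_end = nchar(q),
            s_start = p, s_end = p + nchar(q),
            strand = "-", mismatches = 0L, gaps = 0L
          )
        }
      }
    }
  }
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- data.frame(
      query_seq = character(), record_id = character(),
      q_start = integer(), q_end = integer(),
      s_start = integer(), s_end = integer(),
      strand = character(), mismatches = integer(), gaps = integer()
    )
  }
  unique(res)
}

sort_hits <- function(h) {
  h <- as.data.frame(h)
  h[order(h$query_seq, h$record_id, h$s_start, h$strand), , drop = FALSE] |>
    `rownames<-`(NULL)
}

# brute-force row predicate for the CPM filter
brute_filter_keep <- function(counts_row, lib_sizes, cutoff_cpm, min_samples) {
  ok <- 0L
  for (j in seq_along(counts_row)) {
    if (counts_row[j] / lib_sizes[j] * 1e6 >= cutoff_cpm) ok <- ok + 1L
  }
  ok >= min_samples
}

random_seq_chr <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}
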