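ANNOT_SPECIES <- c("pig", "cattle", "human")
ANNOT_CLASSES <- c(
  "mirna_mature", "mirna_precursor", "rrna", "trna",
  "pirna_cluster", "mrna", "other_ncrna"
)
ANNOT_TIERS <- c("known", "predicted", "orthologue")

# species/tier precedence for miRNA labels (lower = preferred)
ORIGIN_LEVELS <- c(
  "pig-known", "pig-predicted", "cattle-orthologue", "human-orthologue"
)

#' Build a validated reference collection
#'
#' A reference collection is a tibble of sequences tagged with species,
#' RNA class and source tier, the prioritized multi-species database the
#' annotation step searches. Sequences are normalized to uppercase DNA
#' (U -> T), as miRBase ships RNA-alphabet FASTA.
#'
#' @param record_id Unique record identifiers.
#' @param species One of `"pig"`, `"cattle"`, `"human"` per record.
#' @param rna_class One of `"mirna_mature"`, `"mirna_precursor"`,
#'   `"rrna"`, `"trna"`, `"pirna_cluster"`, `"mrna"`, `"other_ncrna"`.
#' @param tier One of `"known"`, `"predicted"`, `"orthologue"`; the pig
#'   (target species) never carries the `"orthologue"` tier.
#' @param sequence Nucleotide sequences.
#'
#' @return A `reference_records` tibble.
#' @export
reference_records <- function(record_id, species, rna_class, tier, sequence) {
  refs <- tibble(
    record_id = as.character(record_id),
    species = as.character(species),
    rna_class = as.character(rna_class),
    tier = as.character(tier),
    sequence = normalize_seq(as.character(sequence))
  )
  if (anyDuplicated(refs$record_id)) {
    abort(paste0(
      "duplicate record_id: ",
      refs$record_id[duplicated(refs$record_id)][1]
    ))
  }
  if (!all(refs$species %in% ANNOT_SPECIES)) abort("unknown species in references")
  if (!all(refs$rna_class %in% ANNOT_CLASSES)) abort("unknown rna_class in references")
  if (!all(refs$tier %in% ANNOT_TIERS)) abort("unknown tier in references")
  if (any(refs$species == "pig" & refs$tier == "orthologue")) {
    abort("pig references cannot carry the 'orthologue' tier")
  }
  if (any(!nzchar(refs$sequence))) abort("empty reference sequence")
  class(refs) <- c("reference_records", class(refs))
  refs
}

#' Read a reference collection from FASTA plus manifest
#'
#' FASTA headers are matched to the first whitespace-delimited token; the
#' tab-separated manifest (columns `record_id`, `species`, `rna_class`,
#' `tier`) supplies the metadata, avoiding any parsing of database-specific
#' header dialects.
#'
#' @param fasta Path to a FASTA file.
#' @param manifest Path to the manifest TSV.
#' @return A `reference_records` tibble.
#' @export
read_reference_fasta <- function(fasta, manifest) {
  seqs <- Biostrings::readBStringSet(fasta)
  ids <- sub("\\s.*$", "", names(seqs))
  man <- readr::read_tsv(manifest, show_col_types = FALSE)
  need <- c("record_id", "species", "rna_class", "tier")
  if (!all(need %in% names(man))) {
    abort("manifest needs columns record_id, species, rna_class, tier")
  }
  miss <- setdiff(man$record_id, ids)
  if (length(miss)) abort(paste0("manifest record not in FASTA: ", miss[1]))
  reference_records(
    record_id = man$record_id,
    species = man$species,
    rna_class = man$rna_class,
    tier = man$tier,
    sequence = as.character(seqs)[match(man$record_id, ids)]
  )
}

#' Write a reference collection to FASTA plus manifest
#'
#' @param refs A `reference_records` tibble.
#' @param fasta,manifest Output paths.
#' @return `fasta`, invisibly.
#' @export
write_reference_fasta <- function(refs, fasta, manifest) {
  x <- Biostrings::DNAStringSet(refs$sequence)
  names(x) <- refs$record_id
  Biostrings::writeXStringSet(x, fasta)
  readr::write_tsv(
    refs[c("record_id", "species", "rna_class", "tier")], manifest
  )
  invisible(fasta)
}

#' Exact full-query search against a reference collection
#'
#' Finds every ungapped, mismatch-free occurrence of each full query
#' inside a reference sequence — the post-filter equivalent of a
#' blastn-short search in which alignments with any mismatch or gap are
#' discarded. Queries containing `N` never match (no wildcard semantics).
#' Mature and precursor miRNA references (and other transcript classes)
#' are matched on the plus strand only; for genomic-context classes
#' (`pirna_cluster`, `mrna`) the reverse complement of the query is also
#' searched, reported with `strand == "-"` and subject coordinates on the
#' plus strand. Duplicate hits are removed. Coordinates are 0-based,
#' half-open.
#'
#' @param queries Character vector of query sequences (ACGTN alphabet).
#' @param refs A `reference_records` tibble.
#' @param minus_strand_classes RNA classes additionally searched on the
#'   minus strand.
#'
#' @return A tibble of hits: `query_seq`, `record_id`, `q_start`, `q_end`,
#'   `s_start`, `s_end`, `strand`, `mismatches` (always 0), `gaps`
#'   (always 0).
#' @export
search_hits <- function(queries, refs,
                        minus_strand_classes = c("pirna_cluster", "mrna")) {
  queries <- unique(as.character(queries))
  if (any(grepl("[^ACGTN]", queries))) {
    abort("queries must contain only A, C, G, T or N")
  }
  empty_hits <- tibble(
    query_seq = character(), record_id = character(),
    q_start = integer(), q_end = integer(),
    s_start = integer(), s_end = integer(),
    strand = character(), mismatches = integer(), gaps = integer()
  )
  searchable <- queries[!grepl("N", queries, fixed = TRUE) & nzchar(queries)]
  if (!length(searchable) || !nrow(refs)) return(empty_hits)

  pats <- Biostrings::DNAStringSet(searchable)
  pd <- Biostrings::PDict(
    pats, tb.start = 1L, tb.end = min(Biostrings::width(pats))
  )
  minus_idx <- which(refs$rna_class %in% minus_strand_classes)
  pd_rc <- NULL
  if (length(minus_idx)) {
    pd_rc <- Biostrings::PDict(
      Biostrings::reverseComplement(pats),
      tb.start = 1L, tb.end = min(Biostrings::width(pats))
    )
  }

  one_ref <- function(i, dict, strand) {
    subject <- Biostrings::DNAString(refs$sequence[i])
    m <- Biostrings::matchPDict(dict, subject, max.mismatch = 0)
    starts <- Biostrings::startIndex(m)
    hit_q <- which(lengths(starts) > 0L)
    if (!length(hit_q)) return(NULL)
    qlen <- nchar(searchable[hit_q])
    nhit <- lengths(starts[hit_q])
    tibble(
      query_seq = rep(searchable[hit_q], nhit),
      record_id = refs$record_id[i],
      q_start = 0L,
      q_end = rep(qlen, nhit),
      s_start = unlist(starts[hit_q]) - 1L,
      s_end = unlist(starts[hit_q]) - 1L + rep(qlen, nhit),
      strand = strand,
      mismatches = 0L,
      gaps = 0L
    )
  }

  plus <- lapply(seq_len(nrow(refs)), one_ref, dict = pd, strand = "+")
  minus <- lapply(minus_idx, one_ref, dict = pd_rc, strand = "-")
  hits <- bind_rows(c(plus, minus))
  if (!nrow(hits)) return(empty_hits)
  distinct(hits)
}

origin_label <- function(species, tier) paste(species, tier, sep = "-")

#' Resolve hits into per-sequence annotations
#'
#' Applies the false-miRNA exclusion rule first: a query with both a miRNA
#' hit and a hit to pig tRNA or to pig/human rRNA is removed from the
#' miRNA class (`excluded_as` records why) and labelled with the
#' contaminant class. Otherwise the class follows the fixed priority
#' miRNA > tRNA > rRNA > piRNA cluster > mRNA > other ncRNA. miRNA
#' species/tier labels follow the precedence pig-known > pig-predicted >
#' cattle-orthologue > human-orthologue; all miRNA hits are retained in
#' the `mirna_assignments` list-column for isomiR processing. Queries
#' shorter than `min_query_len` are reported unannotated.
#'
#' @param queries Character vector of query sequences.
#' @param hits Hit tibble from [search_hits()].
#' @param refs The reference collection searched.
#' @param min_query_len Queries shorter than this are never annotated
#'   (default 16; guards against spurious exact matches).
#'
#' @return A tibble with one row per query: `query_seq`, `rna_class`
#'   (resolved class or `"unannotated"`), `species`, `tier` (of the best
#'   miRNA assignment, else `NA`), `excluded_as` (`"trna_hit"`,
#'   `"rrna_hit"` or `NA`) and `mirna_assignments` (list-column of
#'   tibbles: `record_id`, `species`, `tier`, `mature_or_precursor`).
#' @export
resolve_hits <- function(queries, hits, refs, min_query_len = 16L) {
  queries <- unique(as.character(queries))
  info <- hits |>
    inner_join(
      refs[c("record_id", "species", "rna_class", "tier")],
      by = "record_id"
    )
  empty_assign <- tibble(
    record_id = character(), species = character(),
    tier = character(), mature_or_precursor = character()
  )

  # per-query flags, order-independent by construction
  flags <- info |>
    group_by(query_seq = .data$query_seq) |>
    summarise(
      has_mature = any(.data$rna_class == "mirna_mature"),
      has_precursor = any(.data$rna_class == "mirna_precursor"),
      excl_trna = any(.data$rna_class == "trna" & .data$species == "pig"),
      excl_rrna = any(.data$rna_class == "rrna" &
        .data$species %in% c("pig", "human")),
      has_trna = any(.data$rna_class == "trna"),
      has_rrna = any(.data$rna_class == "rrna"),
      has_pirna = any(.data$rna_class == "pirna_cluster"),
      has_mrna = any(.data$rna_class == "mrna"),
      has_other = any(.data$rna_class == "other_ncrna"),
      .groups = "drop"
    )
  res <- tibble(query_seq = queries) |>
    left_join(flags, by = "query_seq") |>
    mutate(across(-"query_seq", ~ tidyr::replace_na(.x, FALSE)))

  is_mir <- res$has_mature | res$has_precursor
  excluded <- is_mir & (res$excl_trna | res$excl_rrna)
  rna_class <- rep("unannotated", nrow(res))
  rna_class[res$has_other] <- "other_ncrna"
  rna_class[res$has_mrna] <- "mrna"
  rna_class[res$has_pirna] <- "pirna_cluster"
  rna_class[res$has_rrna] <- "rrna"
  rna_class[res$has_trna] <- "trna"
  rna_class[is_mir & !excluded] <-
    ifelse(res$has_mature[is_mir & !excluded], "mirna_mature", "mirna_precursor")
  rna_class[excluded] <- ifelse(res$excl_trna[excluded], "trna", "rrna")
  excluded_as <- rep(NA_character_, nrow(res))
  excluded_as[excluded] <- ifelse(res$excl_trna[excluded], "trna_hit", "rrna_hit")
  short <- nchar(res$query_seq) < min_query_len
  rna_class[short] <- "unannotated"
  excluded_as[short] <- NA_character_

  out <- tibble(
    query_seq = res$query_seq,
    rna_class = rna_class,
    species = NA_character_,
    tier = NA_character_,
    excluded_as = excluded_as,
    mirna_assignments = rep(list(empty_assign), nrow(res))
  )

  # assignment lists only for sequences that stay in the miRNA class
  mir_q <- out$query_seq[out$rna_class %in% c("mirna_mature", "mirna_precursor")]
  if (length(mir_q)) {
    mh <- info |>
      filter(
        .data$query_seq %in% mir_q,
        .data$rna_class %in% c("mirna_mature", "mirna_precursor")
      ) |>
      mutate(
        mature_or_precursor =
          ifelse(.data$rna_class == "mirna_mature", "mature", "precursor")
      ) |>
      distinct(
        .data$query_seq, .data$record_id, .data$species, .data$tier,
        .data$mature_or_precursor
      ) |>
      mutate(
        prec = match(origin_label(.data$species, .data$tier), ORIGIN_LEVELS),
        mat = .data$mature_or_precursor == "mature"
      ) |>
      # a mature assignment outranks any precursor-only assignment: a
      # sequence matching an orthologue mature inside a pig precursor is a
      # novel mature of a known gene, labelled by its mature
      arrange(dplyr::desc(.data$mat), .data$prec, .data$record_id) |>
      select(-"prec", -"mat")
    split_assign <- split(
      mh[c("record_id", "species", "tier", "mature_or_precursor")],
      mh$query_seq
    )
    idx <- match(names(split_assign), out$query_seq)
    out$mirna_assignments[idx] <- split_assign
    out$species[idx] <- vapply(split_assign, function(a) a$species[1], "")
    out$tier[idx] <- vapply(split_assign, function(a) a$tier[1], "")
  }
  out
}

#' Annotate unique sequences against a reference collection
#'
#' Convenience wrapper: [search_hits()] then [resolve_hits()]. With
#' `edit1_exclusion = TRUE` the tRNA/rRNA exclusion additionally removes
#' miRNA-classified sequences lying within edit distance 1 of a
#' subsequence of an excluding reference (off by default; the strict rule
#' is exact occurrence).
#'
#' @inheritParams resolve_hits
#' @param refs A `reference_records` tibble.
#' @param edit1_exclusion Also exclude near-matches (edit distance <= 1)
#'   to pig tRNA / pig+human rRNA. Default `FALSE`.
#' @return See [resolve_hits()].
#' @export
annotate_sequences <- function(queries, refs, min_query_len = 16L,
                               edit1_exclusion = FALSE) {
  queries <- unique(as.character(queries))
  hits <- search_hits(queries, refs)
  res <- resolve_hits(queries, hits, refs, min_query_len = min_query_len)
  if (edit1_exclusion) {
    excl_refs <- refs[
      (refs$rna_class == "trna" & refs$species == "pig") |
        (refs$rna_class == "rrna" & refs$species %in% c("pig", "human")),
      ,
      drop = FALSE
    ]
    idx <- which(res$rna_class %in% c("mirna_mature", "mirna_precursor"))
    if (nrow(excl_refs) && length(idx)) {
      subjects <- Biostrings::DNAStringSet(excl_refs$sequence)
      for (i in idx) {
        nearby <- Biostrings::vcountPattern(
          res$query_seq[i], subjects,
          max.mismatch = 1, with.indels = TRUE
        )
        near_trna <- any(nearby > 0 & excl_refs$rna_class == "trna")
        near_rrna <- any(nearby > 0 & excl_refs$rna_class == "rrna")
        if (near_trna || near_rrna) {
          res$excluded_as[i] <- if (near_trna) "trna_hit" else "rrna_hit"
          res$rna_class[i] <- if (near_trna) "trna" else "rrna"
          res$species[i] <- NA_character_
          res$tier[i] <- NA_character_
          res$mirna_assignments[i] <- list(res$mirna_assignments[[1]][0, ])
        }
      }
    }
  }
  res
}

collapse_class <- function(rna_class) {
  ifelse(rna_class %in% c("mirna_mature", "mirna_precursor"), "mirna", rna_class)
}

#' Summarize annotation classes over a count table
#'
#' Per RNA class: number and percentage of unique sequences, summed read
#' counts and percentage of reads; plus per-sample read-count proportions
#' per class. Percentages partition 100% over all classes including the
#' unannotated bucket.
#'
#' @param results Annotation tibble from [annotate_sequences()].
#' @param table Count table whose `sequence` column matches
#'   `results$query_seq`.
#' @return A `class_summary` object: list with tibbles `overall`
#'   (`rna_class`, `n_unique`, `pct_unique`, `reads`, `pct_reads`) and
#'   `per_sample` (`sample_id`, `rna_class`, `reads`, `pct_reads`).
#' @export
summarize_classes <- function(results, table) {
  ids <- setdiff(names(table), "sequence")
  missing <- setdiff(table$sequence, results$query_seq)
  if (length(missing)) {
    abort("every sequence in the table needs an annotation result")
  }
  long <- table |>
    tidyr::pivot_longer(all_of(ids), names_to = "sample_id", values_to = "count") |>
    left_join(
      results |>
        mutate(class = collapse_class(.data$rna_class)) |>
        select(sequence = "query_seq", "class"),
      by = "sequence"
    )
  overall <- long |>
    group_by(rna_class = .data$class) |>
    summarise(
      n_unique = dplyr::n_distinct(.data$sequence),
      reads = sum(.data$count),
      .groups = "drop"
    ) |>
    mutate(
      pct_unique = 100 * .data$n_unique / sum(.data$n_unique),
      pct_reads = if (sum(.data$reads) > 0) 100 * .data$reads / sum(.data$reads) else 0
    ) |>
    select("rna_class", "n_unique", "pct_unique", "reads", "pct_reads") |>
    arrange(dplyr::desc(.data$n_unique))
  per_sample <- long |>
    group_by(sample_id = .data$sample_id, rna_class = .data$class) |>
    summarise(reads = sum(.data$count), .groups = "drop_last") |>
    mutate(pct_reads = if (sum(.data$reads) > 0) 100 * .data$reads / sum(.data$reads) else 0) |>
    ungroup()
  structure(
    list(overall = overall, per_sample = per_sample),
    class = "class_summary"
  )
}

#' Breakdown of miRNA annotations by species and novelty
#'
#' Counts miRNA-annotated sequences by origin precedence class
#' (pig-known, pig-predicted, cattle-orthologue, human-orthologue — the
#' orthologue classes are "novel for pig"), the number of distinct mature
#' miRNAs represented, and how many orthologue-only matures nevertheless
#' lie within a pig precursor ("novel mature miRNA of a known gene").
#'
#' @param results Annotation tibble from [annotate_sequences()].
#' @return A `novelty_summary` object: list with `by_origin` tibble
#'   (`origin`, `n_sequences`, `pct`), `n_mature_mirnas`,
#'   `novel_mature_known_precursor`.
#' @export
novelty_breakdown <- function(results) {
  mir <- results[results$rna_class %in% c("mirna_mature", "mirna_precursor"), ,
    drop = FALSE
  ]
  origin <- factor(
    origin_label(mir$species, mir$tier),
    levels = ORIGIN_LEVELS
  )
  by_origin <- tibble(origin = origin) |>
    count(.data$origin, name = "n_sequences", .drop = FALSE) |>
    mutate(pct = if (nrow(mir)) 100 * .data$n_sequences / nrow(mir) else 0)

  best <- lapply(mir$mirna_assignments, function(a) a[1, , drop = FALSE])
  best <- bind_rows(best)
  matures <- unlist(lapply(mir$mirna_assignments, function(a) {
    a$record_id[a$mature_or_precursor == "mature"][1]
  }))
  n_mature <- dplyr::n_distinct(matures[!is.na(matures)])

  novel_known_pre <- 0L
  if (nrow(mir)) {
    for (i in seq_len(nrow(mir))) {
      a <- mir$mirna_assignments[[i]]
      if (!nrow(a)) next
      if (a$species[1] != "pig" && a$mature_or_precursor[1] == "mature" &&
        any(a$species == "pig" & a$mature_or_precursor == "precursor")) {
        novel_known_pre <- novel_known_pre + 1L
      }
    }
  }
  structure(
    list(
      by_origin = by_origin,
      n_mature_mirnas = n_mature,
      novel_mature_known_precursor = novel_known_pre
    ),
    class = "novelty_summary"
  )
}
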