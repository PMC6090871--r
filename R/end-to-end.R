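#' Run the full pipeline on simulated data and score it against truth
#'
#' Simulates a library with [simulate_srna()], runs
#' preprocess -> count table -> CPM filter -> annotation -> isomiR calling,
#' and scores three things against the ground truth:
#'
#' * **class assignment**: among filtered unique sequences that received
#'   an annotation (and are not planted dual-hit cases), the fraction
#'   whose class matches the truth label. Sequences carrying
#'   non-templated tails cannot match any reference exactly and stay
#'   unannotated by design; `annotated_fraction` reports how many
#'   sequences were annotatable at all.
#' * **exclusion rule**: every miRNA-derived sequence that also occurs
#'   verbatim inside a pig tRNA or pig/human rRNA reference must be
#'   excluded from the miRNA class; any excluded miRNA sequence *not*
#'   occurring in such a reference is a false exclusion.
#' * **isomiR recovery**: [call_isomir()] applied to each truth-labelled
#'   miRNA insert against its true group must reproduce
#'   (`five_offset`, `three_offset`, `five_tail`, `three_tail`) exactly;
#'   the rate is read-weighted and restricted to inserts whose templated
#'   core occurs uniquely in the precursor and whose tails are < 5 nt.
#'
#' @param cfg A [sim_config()].
#' @param target_reads Average per-library read count used to derive the
#'   CPM cutoff for the low-evidence filter (default 2 at desk scale).
#' @param min_samples Minimum number of libraries passing the cutoff
#'   (default 1).
#' @return A `recovery_report` list: `class` (tibble with
#'   `annotated_fraction`, `class_accuracy`), `exclusion` (tibble with
#'   `n_dual_hit`, `n_excluded`, `exclusion_rate`, `n_false_exclusions`),
#'   `isomir` (tibble with `n_sequences`, `n_reads`, `recovery_rate`),
#'   plus the intermediate `table`, `annotation` and `records`.
#' @export
end_to_end_check <- function(cfg = sim_config(), target_reads = 2,
                             min_samples = 1L) {
  sim <- simulate_srna(cfg)

  collapsed <- lapply(unique(sim$reads$sample_id), function(s) {
    sim$reads[sim$reads$sample_id == s, ] |>
      clip_adapter(adapter = cfg$adapter, min_len = 16L) |>
      trim_leading_n() |>
      collapse_reads(s)
  })
  table <- join_samples(collapsed) |>
    filter_table(target_reads = target_reads, min_samples = min_samples)

  annot <- annotate_sequences(table$sequence, sim$refs)

  ## --- truth per unique sequence --------------------------------------
  truth_seq <- sim$truth |>
    group_by(sequence = .data$insert) |>
    summarise(
      truth_class = if (dplyr::n_distinct(.data$rna_class) == 1L) {
        .data$rna_class[1]
      } else {
        NA_character_
      },
      from_planted = any(.data$record_id %in% sim$planted$mature_id),
      .groups = "drop"
    )

  # independent re-search oracle: plain fixed-string scans, no shared code
  # with the search engine
  excl_seqs <- sim$refs$sequence[
    (sim$refs$rna_class == "trna" & sim$refs$species == "pig") |
      (sim$refs$rna_class == "rrna" & sim$refs$species %in% c("pig", "human"))
  ]
  mir_ref_seqs <- sim$refs$sequence[
    sim$refs$rna_class %in% c("mirna_mature", "mirna_precursor")
  ]
  occurs_in <- function(q, refs) any(grepl(q, refs, fixed = TRUE))

  scored <- annot |>
    rename(sequence = "query_seq") |>
    left_join(truth_seq, by = "sequence") |>
    mutate(pred_class = collapse_class(.data$rna_class))

  dual_hit <- vapply(scored$sequence, function(q) {
    occurs_in(q, excl_seqs) && occurs_in(q, mir_ref_seqs)
  }, TRUE, USE.NAMES = FALSE)
  is_excluded <- !is.na(scored$excluded_as)

  excl_tab <- tibble(
    n_dual_hit = sum(dual_hit),
    n_excluded = sum(dual_hit & is_excluded),
    exclusion_rate = ifelse(sum(dual_hit) > 0,
      sum(dual_hit & is_excluded) / sum(dual_hit), NA_real_
    ),
    n_false_exclusions = sum(is_excluded & !dual_hit),
    n_mirna_with_contaminant_hit = sum(
      scored$rna_class %in% c("mirna_mature", "mirna_precursor") & dual_hit
    )
  )

  # planted-locus variants are deliberately ambiguous (their tails can match
  # the contaminant context); they are scored by the exclusion metric instead
  acc <- scored |>
    filter(
      !is.na(.data$truth_class),
      !.data$from_planted,
      .data$pred_class != "unannotated",
      is.na(.data$excluded_as),
      !.env$dual_hit
    )
  class_tab <- tibble(
    n_sequences = nrow(scored),
    annotated_fraction = mean(scored$pred_class != "unannotated"),
    class_accuracy = if (nrow(acc)) {
      mean(acc$pred_class == acc$truth_class)
    } else {
      NA_real_
    }
  )

  ## --- isomiR recovery against the true groups ------------------------
  iso <- isomir_recovery(sim)

  structure(
    list(
      class = class_tab,
      exclusion = excl_tab,
      isomir = iso$summary,
      table = table,
      annotation = annot,
      records = iso$records
    ),
    class = "recovery_report"
  )
}

# score call_isomir() against truth labels, read-weighted
isomir_recovery <- function(sim) {
  mir <- sim$truth[sim$truth$rna_class == "mirna", , drop = FALSE]
  loci <- sim$truth |>
    filter(.data$rna_class == "mirna") |>
    distinct(.data$group_id)

  # group geometry from the reference collection
  refs <- sim$refs
  geom <- purrr::map_dfr(loci$group_id, function(g) {
    parts <- strsplit(g, "|", fixed = TRUE)[[1]]
    if (parts[2] == "mature-only") {
      mseq <- refs$sequence[refs$record_id == parts[1]]
      tibble(
        group_id = g, precursor_seq = mseq,
        mature_start = 0L, mature_end = nchar(mseq)
      )
    } else {
      pseq <- refs$sequence[refs$record_id == parts[1]]
      mseq <- refs$sequence[refs$record_id == parts[2]]
      at <- as.integer(regexpr(mseq, pseq, fixed = TRUE)) - 1L
      tibble(
        group_id = g, precursor_seq = pseq,
        mature_start = at, mature_end = at + nchar(mseq)
      )
    }
  })

  uniq <- mir |>
    count(.data$group_id, .data$insert,
      .data$five_offset, .data$three_offset, .data$five_tail, .data$three_tail,
      name = "n_reads"
    ) |>
    left_join(geom, by = "group_id")

  core <- substr(
    uniq$precursor_seq,
    uniq$mature_start + uniq$five_offset + 1L,
    uniq$mature_end + uniq$three_offset
  )
  core_unique <- vapply(seq_len(nrow(uniq)), function(i) {
    length(gregexpr(core[i], uniq$precursor_seq[i], fixed = TRUE)[[1]]) == 1L
  }, TRUE)
  short_tails <- nchar(uniq$five_tail) < 5L & nchar(uniq$three_tail) < 5L
  eval_set <- uniq[core_unique & short_tails, , drop = FALSE]

  calls <- purrr::map_dfr(seq_len(nrow(eval_set)), function(i) {
    r <- call_isomir(
      eval_set$insert[i], eval_set$precursor_seq[i],
      eval_set$mature_start[i], eval_set$mature_end[i]
    )
    if (is.null(r)) {
      return(tibble(
        called = FALSE, five_offset_hat = NA_integer_,
        three_offset_hat = NA_integer_,
        five_tail_hat = NA_character_, three_tail_hat = NA_character_
      ))
    }
    tibble(
      called = TRUE,
      five_offset_hat = r$five_offset, three_offset_hat = r$three_offset,
      five_tail_hat = r$five_tail, three_tail_hat = r$three_tail
    )
  })
  records <- bind_cols(eval_set, calls) |>
    mutate(recovered = .data$called &
      .data$five_offset_hat == .data$five_offset &
      .data$three_offset_hat == .data$three_offset &
      .data$five_tail_hat == .data$five_tail &
      .data$three_tail_hat == .data$three_tail) |>
    mutate(recovered = tidyr::replace_na(.data$recovered, FALSE))

  list(
    records = records,
    summary = tibble(
      n_sequences = nrow(records),
      n_reads = sum(records$n_reads),
      recovery_rate = sum(records$n_reads * records$recovered) /
        sum(records$n_reads)
    )
  )
}
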