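#' Summarize the isomiR repertoire
#'
#' Aggregates isomiR records into the standard end-variant summaries:
#' the modification-class partition (canonical / 5' only / 3' only /
#' both), templated vs non-templated counts with the per-end breakdown of
#' non-templated forms, added/deleted length histograms per end, base
#' composition of added and deleted nucleotides per end, per-group isomiR
#' counts, and the rank-1 breakdown (which modification class is the most
#' expressed isomiR, separately for groups that do and do not contain the
#' canonical form).
#'
#' Records from mature-only groups (templating unverifiable) are excluded
#' from all of the above and reported separately in `$mature_only`.
#'
#' @param records IsomiR record tibble from [call_isomirs()].
#' @param groups Group tibble from [build_groups()] (supplies precursor
#'   and mature sequences for base composition).
#'
#' @return An `isomir_summary` object: list with elements `mod_class`,
#'   `nontemplated_by_end`, `end_changes`, `base_composition`,
#'   `per_group`, `rank1_by_canonical`, `rank1_by_templated`,
#'   `mature_only`, `totals`.
#' @export
summarize_isomirs <- function(records, groups) {
  mature_only_n <- sum(!records$precursor_available)
  recs <- records[records$precursor_available, , drop = FALSE]

  mod_levels <- c("canonical", "five_only", "three_only", "both")
  mod_class <- recs |>
    mutate(mod_class = factor(.data$mod_class, levels = mod_levels)) |>
    count(.data$mod_class, name = "n", .drop = FALSE) |>
    mutate(pct = if (nrow(recs)) 100 * .data$n / nrow(recs) else 0)

  nt_end <- dplyr::case_when(
    nzchar(recs$five_tail) & nzchar(recs$three_tail) ~ "both",
    nzchar(recs$five_tail) ~ "five",
    nzchar(recs$three_tail) ~ "three",
    TRUE ~ NA_character_
  )
  nontemplated_by_end <- tibble(
    end = factor(nt_end, levels = c("five", "three", "both"))
  ) |>
    filter(!is.na(.data$end)) |>
    count(.data$end, name = "n", .drop = FALSE)

  ginfo <- groups[c(
    "group_id", "precursor_seq", "mature_seq", "mature_start", "mature_end"
  )]
  r <- left_join(recs, ginfo, by = "group_id") |>
    mutate(
      five_added_templated = ifelse(
        .data$five_offset < 0L,
        substr(.data$precursor_seq, .data$aligned_start + 1L, .data$mature_start),
        ""
      ),
      three_added_templated = ifelse(
        .data$three_offset > 0L,
        substr(.data$precursor_seq, .data$mature_end + 1L, .data$aligned_end),
        ""
      ),
      five_added = paste0(.data$five_tail, .data$five_added_templated),
      three_added = paste0(.data$three_added_templated, .data$three_tail),
      five_deleted = ifelse(
        .data$five_offset > 0L, substr(.data$mature_seq, 1L, .data$five_offset), ""
      ),
      three_deleted = ifelse(
        .data$three_offset < 0L,
        substr(
          .data$mature_seq,
          nchar(.data$mature_seq) + .data$three_offset + 1L,
          nchar(.data$mature_seq)
        ),
        ""
      )
    )

  end_changes <- bind_rows(
    tibble(end = "five", change = "added", length = nchar(r$five_added)),
    tibble(end = "five", change = "deleted", length = nchar(r$five_deleted)),
    tibble(end = "three", change = "added", length = nchar(r$three_added)),
    tibble(end = "three", change = "deleted", length = nchar(r$three_deleted))
  ) |>
    filter(.data$length > 0L) |>
    count(.data$end, .data$change, .data$length, name = "n")

  tally_bases <- function(x) {
    b <- strsplit(paste(x, collapse = ""), "")[[1]]
    tibble(base = factor(b, levels = c("A", "C", "G", "T"))) |>
      count(.data$base, name = "n", .drop = FALSE) |>
      mutate(fraction = if (length(b)) .data$n / length(b) else 0)
  }
  base_composition <- bind_rows(
    mutate(tally_bases(r$five_added), end = "five", change = "added"),
    mutate(tally_bases(r$five_deleted), end = "five", change = "deleted"),
    mutate(tally_bases(r$three_added), end = "three", change = "added"),
    mutate(tally_bases(r$three_deleted), end = "three", change = "deleted")
  ) |>
    select("end", "change", "base", "n", "fraction")

  per_group <- recs |> count(.data$group_id, name = "n_isomirs")

  rank1 <- if (nrow(recs)) {
    recs |>
      group_by(.data$group_id) |>
      summarise(
        canonical_present = any(.data$mod_class == "canonical"),
        rank1_class = .data$mod_class[which.min(.data$rank)],
        rank1_templated = .data$templated[which.min(.data$rank)],
        .groups = "drop"
      )
  } else {
    tibble(
      group_id = character(), canonical_present = logical(),
      rank1_class = character(), rank1_templated = logical()
    )
  }
  rank1_by_canonical <- rank1 |>
    mutate(rank1_class = factor(.data$rank1_class, levels = mod_levels)) |>
    count(.data$canonical_present, .data$rank1_class, name = "n_groups",
      .drop = FALSE
    ) |>
    group_by(.data$canonical_present) |>
    mutate(pct = ifelse(sum(.data$n_groups) > 0,
      100 * .data$n_groups / sum(.data$n_groups), 0
    )) |>
    ungroup()
  rank1_by_templated <- rank1 |> count(.data$rank1_templated, name = "n_groups")

  structure(
    list(
      mod_class = mod_class,
      nontemplated_by_end = nontemplated_by_end,
      end_changes = end_changes,
      base_composition = base_composition,
      per_group = per_group,
      rank1_by_canonical = rank1_by_canonical,
      rank1_by_templated = rank1_by_templated,
      mature_only = tibble(n_records = mature_only_n),
      totals = tibble(
        n_isomirs = nrow(recs),
        n_groups = dplyr::n_distinct(recs$group_id),
        mean_isomirs_per_group = if (nrow(per_group)) mean(per_group$n_isomirs) else NA_real_,
        n_templated = sum(recs$templated, na.rm = TRUE),
        n_nontemplated = sum(!recs$templated, na.rm = TRUE)
      )
    ),
    class = "isomir_summary"
  )
}

#' Aggregate isomiR counts to per-miRNA count tables
#'
#' Sums the per-sample counts of all member isomiRs of each miRNA group.
#' Multi-mapped sequences contribute once to every group they belong to;
#' the resulting double counting is flagged per group in
#' `has_multimapped_members` rather than silently dropped.
#'
#' @param records IsomiR record tibble from [call_isomirs()].
#' @param table Unique-sequence count table (filtered).
#' @return A tibble: `group_id`, one column per sample, and
#'   `has_multimapped_members`. Feed to [as_edger_counts()] with
#'   `id_col = "group_id"` for edgeR.
#' @export
aggregate_to_mirna <- function(records, table) {
  ids <- setdiff(names(table), "sequence")
  long <- table |>
    tidyr::pivot_longer(all_of(ids), names_to = "sample_id", values_to = "count") |>
    inner_join(
      records[c("group_id", "query_seq", "multi_mapped")],
      by = c(sequence = "query_seq"),
      relationship = "many-to-many"
    )
  agg <- long |>
    group_by(.data$group_id, .data$sample_id) |>
    summarise(count = sum(.data$count), .groups = "drop") |>
    mutate(sample_id = factor(.data$sample_id, levels = ids)) |>
    tidyr::pivot_wider(
      names_from = "sample_id", values_from = "count",
      values_fill = 0L, names_expand = TRUE
    )
  flags <- long |>
    group_by(.data$group_id) |>
    summarise(has_multimapped_members = any(.data$multi_mapped), .groups = "drop")
  left_join(agg, flags, by = "group_id")
}
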