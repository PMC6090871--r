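#' Per-miRNA expression profile of a dataset
#'
#' Converts a per-miRNA aggregate count table (see [aggregate_to_mirna()])
#' into total read counts and percentages of all miRNA-assigned reads.
#'
#' @param agg Tibble with an identifier column and per-sample counts, or a
#'   tibble with columns `mirna` and `reads`.
#' @param dataset_id Label for the dataset (e.g. `"embryo_d10"`).
#' @param id_col Identifier column of `agg` (default `"group_id"`).
#' @return A tibble: `dataset_id`, `mirna`, `reads`, `pct`
#'   (percentages sum to 100).
#' @export
expression_profile <- function(agg, dataset_id, id_col = "group_id") {
  if (all(c("mirna", "reads") %in% names(agg))) {
    prof <- tibble(mirna = as.character(agg$mirna), reads = as.numeric(agg$reads))
  } else {
    num <- setdiff(names(agg), id_col)
    num <- num[vapply(agg[num], is.numeric, TRUE)]
    prof <- tibble(
      mirna = as.character(agg[[id_col]]),
      reads = rowSums(as.matrix(agg[num]))
    )
  }
  if (anyDuplicated(prof$mirna)) abort("duplicate miRNA identifiers in profile")
  total <- sum(prof$reads)
  if (total <= 0) abort("profile has no reads")
  prof |>
    mutate(dataset_id = dataset_id, pct = 100 * .data$reads / total) |>
    arrange(dplyr::desc(.data$pct), .data$mirna) |>
    select("dataset_id", "mirna", "reads", "pct")
}

#' Top expressed miRNAs plus an "all remaining" bucket
#'
#' @param profile Profile tibble from [expression_profile()].
#' @param n Number of top miRNAs to report (default 20).
#' @return A `top_expressed` tibble: the top `n` miRNAs by percentage plus
#'   one `"all remaining"` row; percentages sum to 100.
#' @export
top_expressed <- function(profile, n = 20L) {
  if (n < 1L) abort("n must be >= 1")
  ord <- profile |> arrange(dplyr::desc(.data$pct), .data$mirna)
  top <- head(ord, n)
  rest <- ord[-seq_len(min(n, nrow(ord))), , drop = FALSE]
  out <- bind_rows(
    top,
    tibble(
      dataset_id = profile$dataset_id[1] %||% NA_character_,
      mirna = "all remaining",
      reads = sum(rest$reads),
      pct = sum(rest$pct)
    )
  )
  class(out) <- c("top_expressed", class(out))
  out
}

strip_species_prefix <- function(x) sub("^(ssc|bta|hsa)-", "", x)

#' Compare top expressed miRNAs across datasets
#'
#' Takes the union of each dataset's top `n` miRNAs and tabulates their
#' percentage of miRNA-assigned reads per dataset. miRNA names are
#' harmonized across species naming schemes by stripping the
#' `ssc-`/`bta-`/`hsa-` prefix; a collision (two distinct miRNAs of one
#' dataset harmonizing to one name) is an error and must be resolved
#' upstream. A miRNA is labelled `"enriched in <D>"` when its percentage
#' in dataset D is at least `enrich_fold` times its percentage in every
#' other dataset, `"underrepresented in <D>"` in the symmetric case, and
#' `"shared"` otherwise; percentages below `absent_pct` are floored at
#' `absent_pct` for the fold computation (absence treated as "< 0.01%").
#' The fold threshold is this package's own labelling default, not a
#' published rule.
#'
#' @param profiles List of profile tibbles from [expression_profile()]
#'   with distinct `dataset_id`s.
#' @param n Top-n per dataset entering the union (default 10).
#' @param enrich_fold Fold difference declaring enrichment (default 3).
#' @param absent_pct Floor percentage for absent miRNAs (default 0.01).
#' @return A `profile_comparison` tibble: `mirna`, one percentage column
#'   per dataset, `status`.
#' @export
compare_profiles <- function(profiles, n = 10L, enrich_fold = 3,
                             absent_pct = 0.01) {
  if (length(profiles) < 2L) abort("need at least two profiles to compare")
  profiles <- lapply(profiles, function(p) {
    p$mirna <- strip_species_prefix(p$mirna)
    if (anyDuplicated(p$mirna)) {
      abort(paste0(
        "miRNA id collision after prefix harmonization in dataset '",
        p$dataset_id[1], "': ", p$mirna[duplicated(p$mirna)][1]
      ))
    }
    p
  })
  ids <- vapply(profiles, function(p) p$dataset_id[1], "")
  if (anyDuplicated(ids)) abort("profiles must have distinct dataset_ids")

  union_mirnas <- sort(unique(unlist(
    lapply(profiles, function(p) head(arrange(p, dplyr::desc(p$pct))$mirna, n))
  )))
  pct_mat <- vapply(profiles, function(p) {
    v <- p$pct[match(union_mirnas, p$mirna)]
    ifelse(is.na(v), 0, v)
  }, numeric(length(union_mirnas)))
  pct_mat <- matrix(pct_mat,
    nrow = length(union_mirnas),
    dimnames = list(union_mirnas, ids)
  )

  floored <- pmax(pct_mat, absent_pct)
  status <- vapply(seq_along(union_mirnas), function(i) {
    v <- floored[i, ]
    # enrichment checked for every dataset before underrepresentation, so
    # the labelling does not depend on the order the profiles were given
    for (d in seq_along(ids)) {
      if (all(v[d] >= enrich_fold * v[-d])) {
        return(paste0("enriched in ", ids[d]))
      }
    }
    for (d in seq_along(ids)) {
      if (all(v[d] <= v[-d] / enrich_fold)) {
        return(paste0("underrepresented in ", ids[d]))
      }
    }
    "shared"
  }, "")

  out <- bind_cols(
    tibble(mirna = union_mirnas),
    as_tibble(pct_mat),
    tibble(status = status)
  )
  class(out) <- c("profile_comparison", class(out))
  out
}
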