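#' Group miRNA-annotated sequences under their precursor and canonical mature
#'
#' Builds one group per (canonical mature, precursor) pair. Pairing is by
#' exact containment of the mature sequence in a same-species precursor
#' (or taken from an explicit `pairs` table, which is validated). A mature
#' contained in two distinct precursors yields two groups, and sequences
#' assigned to both are flagged multi-mapped. A mature with no available
#' precursor (e.g. an orthologue mature without an orthologue precursor)
#' forms a mature-only group: isomiR calls against it cannot distinguish
#' templated from non-templated additions and are reported separately.
#'
#' Group membership derives from each sequence's miRNA hits at its best
#' species/tier precedence level.
#'
#' @param annot Annotation tibble from [annotate_sequences()].
#' @param refs The reference collection.
#' @param pairs Optional tibble (`mature_id`, `precursor_id`) declaring
#'   pairings; a declared mature that does not occur in its precursor is a
#'   reference-integrity error.
#'
#' @return A tibble of groups: `group_id`, `mature_id`, `precursor_id`,
#'   `species`, `tier`, `mature_start`, `mature_end` (0-based half-open
#'   coordinates of the canonical mature within the precursor),
#'   `precursor_seq`, `mature_seq`, `precursor_available`, and a
#'   list-column `members` of tibbles (`query_seq`, `multi_mapped`).
#' @export
build_groups <- function(annot, refs, pairs = NULL) {
  mat <- refs[refs$rna_class == "mirna_mature", , drop = FALSE]
  pre <- refs[refs$rna_class == "mirna_precursor", , drop = FALSE]

  if (is.null(pairs)) {
    pairs <- purrr::map_dfr(seq_len(nrow(mat)), function(i) {
      cand <- pre[pre$species == mat$species[i], , drop = FALSE]
      hit <- which(vapply(
        cand$sequence, function(p) grepl(mat$sequence[i], p, fixed = TRUE), TRUE
      ))
      if (!length(hit)) {
        return(tibble(mature_id = mat$record_id[i], precursor_id = NA_character_))
      }
      tibble(mature_id = mat$record_id[i], precursor_id = cand$record_id[hit])
    })
  } else {
    pairs <- as_tibble(pairs)[c("mature_id", "precursor_id")]
    # matures absent from the declared pairing become mature-only groups
    pairs <- bind_rows(
      pairs,
      tibble(
        mature_id = setdiff(mat$record_id, pairs$mature_id),
        precursor_id = NA_character_
      )
    )
  }

  groups <- purrr::map_dfr(seq_len(nrow(pairs)), function(i) {
    m <- mat[mat$record_id == pairs$mature_id[i], , drop = FALSE]
    if (!nrow(m)) abort(paste0("unknown mature record: ", pairs$mature_id[i]))
    if (is.na(pairs$precursor_id[i])) {
      return(tibble(
        group_id = paste0(m$record_id, "|mature-only"),
        mature_id = m$record_id, precursor_id = NA_character_,
        species = m$species, tier = m$tier,
        mature_start = 0L, mature_end = nchar(m$sequence),
        precursor_seq = m$sequence, mature_seq = m$sequence,
        precursor_available = FALSE
      ))
    }
    p <- pre[pre$record_id == pairs$precursor_id[i], , drop = FALSE]
    if (!nrow(p)) abort(paste0("unknown precursor record: ", pairs$precursor_id[i]))
    occ <- gregexpr(m$sequence, p$sequence, fixed = TRUE)[[1]]
    if (occ[1] == -1L) {
      abort(paste0(
        "reference integrity: mature '", m$record_id,
        "' does not occur in its declared precursor '", p$record_id, "'"
      ))
    }
    tibble(
      group_id = if (length(occ) == 1L) {
        paste0(p$record_id, "|", m$record_id)
      } else {
        paste0(p$record_id, "|", m$record_id, "|occ", seq_along(occ))
      },
      mature_id = m$record_id, precursor_id = p$record_id,
      species = m$species, tier = m$tier,
      mature_start = as.integer(occ) - 1L,
      mature_end = as.integer(occ) - 1L + nchar(m$sequence),
      precursor_seq = p$sequence, mature_seq = m$sequence,
      precursor_available = TRUE
    )
  })

  # membership: hits of each miRNA-annotated sequence at best precedence
  mir <- annot[annot$rna_class %in% c("mirna_mature", "mirna_precursor"), ,
    drop = FALSE
  ]
  membership <- purrr::map_dfr(seq_len(nrow(mir)), function(i) {
    a <- mir$mirna_assignments[[i]]
    if (!nrow(a)) return(NULL)
    prec <- match(origin_label(a$species, a$tier), ORIGIN_LEVELS)
    is_mat <- a$mature_or_precursor == "mature"
    if (any(is_mat)) {
      best <- a[is_mat & prec == min(prec[is_mat]), , drop = FALSE]
      gid <- groups$group_id[groups$mature_id %in% best$record_id]
    } else {
      best <- a[prec == min(prec), , drop = FALSE]
      gid <- groups$group_id[groups$precursor_id %in% best$record_id &
        groups$precursor_available]
    }
    gid <- unique(gid)
    if (!length(gid)) return(NULL)
    tibble(group_id = gid, query_seq = mir$query_seq[i])
  })
  if (nrow(membership)) {
    membership <- membership |>
      distinct() |>
      group_by(.data$query_seq) |>
      mutate(multi_mapped = n() > 1L) |>
      ungroup()
  } else {
    membership <- tibble(
      group_id = character(), query_seq = character(), multi_mapped = logical()
    )
  }
  members <- split(
    membership[c("query_seq", "multi_mapped")], membership$group_id
  )
  groups$members <- rep(
    list(tibble(query_seq = character(), multi_mapped = logical())),
    nrow(groups)
  )
  idx <- match(names(members), groups$group_id)
  groups$members[idx] <- members
  groups
}

#' Call the isomiR end variant of one sequence against its group
#'
#' Places the maximal contiguous core of the query that occurs exactly in
#' the precursor and overlaps the canonical mature locus (deterministic
#' end-anchored extension), then reads off the 5'/3' offsets relative to
#' the canonical mature and the residual non-templated end tails.
#' Ambiguous placements (several cores of maximal length overlapping the
#' locus) resolve to the one minimizing `|five_offset| + |three_offset|`,
#' ties to the smaller `|five_offset|`, then to the leftmost placement.
#'
#' Offset sign convention (mature 5'->3' orientation, 0-based half-open
#' coordinates): `five_offset < 0` means templated nucleotides added
#' upstream of the canonical 5' end, `> 0` means 5' deletions;
#' `three_offset > 0` means templated additions beyond the canonical
#' 3' end, `< 0` means 3' deletions. Non-templated end runs that cannot
#' be explained by the precursor (including any addition beyond the
#' precursor boundary) are returned in `five_tail`/`three_tail`. The
#' record always reconstructs: `five_tail` + precursor core + `three_tail`
#' equals the query.
#'
#' @param query_seq A single sequence (length >= `min_core`).
#' @param precursor_seq Precursor sequence.
#' @param mature_start,mature_end 0-based half-open coordinates of the
#'   canonical mature within the precursor.
#' @param min_core Minimum matching core length (default 16).
#'
#' @return A one-row tibble: `aligned_start`, `aligned_end`,
#'   `five_offset`, `three_offset`, `five_tail`, `three_tail`,
#'   `mod_class` (`canonical`, `five_only`, `three_only`, `both`),
#'   `templated`; or `NULL` when no core of `min_core` nt overlaps the
#'   canonical locus (unassignable).
#' @examples
#' # precursor with canonical mature CCCCGGGG at [4, 12)
#' p <- "AAAACCCCGGGGTTTT"
#' call_isomir("CCCCGGGGT", p, 4, 12, min_core = 8) # templated 3' addition
#' call_isomir("CCCCGGGGA", p, 4, 12, min_core = 8) # non-templated 3' tail
#' @export
call_isomir <- function(query_seq, precursor_seq, mature_start, mature_end,
                        min_core = 16L) {
  q <- query_seq
  p <- precursor_seq
  L <- nchar(q)
  if (L < min_core) return(NULL)

  overlapping_starts <- function(sub, m) {
    occ <- gregexpr(sub, p, fixed = TRUE)[[1]]
    if (occ[1] == -1L) return(integer())
    s0 <- as.integer(occ) - 1L
    s0[s0 < mature_end & s0 + m > mature_start]
  }

  cands <- list()
  best_m <- min_core - 1L
  for (i in 0L:(L - min_core)) {
    if (L - i < best_m) break # shorter than current best: cannot matter
    # maximal m with query[i+1 .. i+m] occurring anywhere in the precursor
    if (!grepl(substr(q, i + 1L, i + min_core), p, fixed = TRUE)) next
    lo <- min_core
    hi <- L - i
    while (lo < hi) {
      mid <- as.integer(ceiling((lo + hi) / 2))
      if (grepl(substr(q, i + 1L, i + mid), p, fixed = TRUE)) lo <- mid else hi <- mid - 1L
    }
    m <- lo
    starts <- overlapping_starts(substr(q, i + 1L, i + m), m)
    # maximal occurrence may lie off-locus while a shorter one overlaps
    while (!length(starts) && m > min_core) {
      m <- m - 1L
      starts <- overlapping_starts(substr(q, i + 1L, i + m), m)
    }
    if (!length(starts)) next
    if (m > best_m) best_m <- m
    cands[[length(cands) + 1L]] <- tibble(i = i, m = m, aligned_start = starts)
  }
  if (!length(cands)) return(NULL)
  cand <- bind_rows(cands) |> filter(.data$m == best_m)
  cand <- cand |>
    mutate(
      aligned_end = .data$aligned_start + .data$m,
      five_offset = .data$aligned_start - mature_start,
      three_offset = .data$aligned_end - mature_end,
      score = abs(.data$five_offset) + abs(.data$three_offset)
    ) |>
    arrange(
      .data$score, abs(.data$five_offset), .data$i, .data$aligned_start
    ) |>
    slice_head(n = 1L)

  five_tail <- substr(q, 1L, cand$i)
  three_tail <- substr(q, cand$i + cand$m + 1L, L)
  five_mod <- cand$five_offset != 0L || nzchar(five_tail)
  three_mod <- cand$three_offset != 0L || nzchar(three_tail)
  tibble(
    aligned_start = cand$aligned_start,
    aligned_end = cand$aligned_end,
    five_offset = cand$five_offset,
    three_offset = cand$three_offset,
    five_tail = five_tail,
    three_tail = three_tail,
    mod_class = if (!five_mod && !three_mod) {
      "canonical"
    } else if (five_mod && three_mod) {
      "both"
    } else if (five_mod) "five_only" else "three_only",
    templated = !nzchar(five_tail) && !nzchar(three_tail)
  )
}

#' Call isomiRs for every group member and rank them by expression
#'
#' Runs [call_isomir()] for each (group, member sequence) pair, attaches
#' total read counts from the count table, and computes the within-group
#' expression rank (rank 1 = highest total count; ties broken by sequence
#' lexicographic order). For mature-only groups, templating cannot be
#' verified and `templated` is `NA`. Members with no placeable core are
#' dropped and reported in the `"unassigned"` attribute.
#'
#' @param groups Group tibble from [build_groups()].
#' @param table Optional count table supplying per-sample counts; when
#'   omitted, `total_count` is `NA` and ranks are by sequence order.
#' @param min_core Minimum matching core length (default 16).
#'
#' @return A tibble of isomiR records: `group_id`, `query_seq`,
#'   `aligned_start`, `aligned_end`, `five_offset`, `three_offset`,
#'   `five_tail`, `three_tail`, `mod_class`, `templated`,
#'   `multi_mapped`, `precursor_available`, `total_count`, `rank`.
#' @export
call_isomirs <- function(groups, table = NULL, min_core = 16L) {
  recs <- purrr::map_dfr(seq_len(nrow(groups)), function(g) {
    mem <- groups$members[[g]]
    if (!nrow(mem)) return(NULL)
    purrr::map_dfr(seq_len(nrow(mem)), function(j) {
      r <- call_isomir(
        mem$query_seq[j], groups$precursor_seq[g],
        groups$mature_start[g], groups$mature_end[g],
        min_core = min_core
      )
      if (is.null(r)) {
        return(tibble(
          group_id = groups$group_id[g], query_seq = mem$query_seq[j],
          aligned_start = NA_integer_, aligned_end = NA_integer_,
          five_offset = NA_integer_, three_offset = NA_integer_,
          five_tail = NA_character_, three_tail = NA_character_,
          mod_class = NA_character_, templated = NA,
          multi_mapped = mem$multi_mapped[j],
          precursor_available = groups$precursor_available[g]
        ))
      }
      bind_cols(
        tibble(group_id = groups$group_id[g], query_seq = mem$query_seq[j]),
        r,
        tibble(
          multi_mapped = mem$multi_mapped[j],
          precursor_available = groups$precursor_available[g]
        )
      )
    })
  })
  if (!nrow(recs)) {
    recs <- tibble(
      group_id = character(), query_seq = character(),
      aligned_start = integer(), aligned_end = integer(),
      five_offset = integer(), three_offset = integer(),
      five_tail = character(), three_tail = character(),
      mod_class = character(), templated = logical(),
      multi_mapped = logical(), precursor_available = logical()
    )
  }
  unassigned <- recs[is.na(recs$mod_class), c("group_id", "query_seq")]
  if (nrow(unassigned)) {
    inform(paste0(
      nrow(unassigned),
      " sequence(s) unassignable to their group (no ", min_core,
      " nt core over the canonical locus); excluded from isomiR records"
    ))
  }
  recs <- recs[!is.na(recs$mod_class), , drop = FALSE]
  recs$templated[!recs$precursor_available] <- NA

  if (!is.null(table)) {
    ids <- setdiff(names(table), "sequence")
    totals <- tibble(
      query_seq = table$sequence,
      total_count = as.integer(rowSums(as.matrix(table[ids])))
    )
    recs <- left_join(recs, totals, by = "query_seq")
    recs$total_count[is.na(recs$total_count)] <- 0L
  } else {
    recs$total_count <- NA_integer_
  }
  recs <- rank_isomirs(recs)
  attr(recs, "unassigned") <- unassigned
  recs
}

#' Rank isomiRs within their miRNA group by read counts
#'
#' Rank 1 is the record with the highest total read count in its group;
#' ties are broken deterministically by sequence lexicographic order.
#'
#' @param records IsomiR record tibble (needs `group_id`, `query_seq`,
#'   `total_count`).
#' @return The records with a `rank` column, ordered by group and rank.
#' @export
rank_isomirs <- function(records) {
  records |>
    group_by(.data$group_id) |>
    arrange(
      dplyr::desc(dplyr::coalesce(.data$total_count, 0L)), .data$query_seq,
      .by_group = TRUE
    ) |>
    mutate(rank = row_number()) |>
    ungroup()
}
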