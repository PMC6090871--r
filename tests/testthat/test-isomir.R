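# handy builder: precursor with a known canonical window
demo_group <- function() {
  flank5 <- "GGATCCAT"
  mature <- "TGAGGTAGTAGGTTGTATAGTT"
  flank3 <- "CTACCTCA"
  list(
    precursor = paste0(flank5, mature, flank3),
    mature = mature,
    start = nchar(flank5),
    end = nchar(flank5) + nchar(mature)
  )
}

test_that("call_isomir resolves the canonical form and templated/non-templated 3' additions", {
  g <- demo_group()

  r0 <- call_isomir(g$mature, g$precursor, g$start, g$end)
  expect_equal(r0$five_offset, 0L)
  expect_equal(r0$three_offset, 0L)
  expect_equal(r0$five_tail, "")
  expect_equal(r0$three_tail, "")
  expect_equal(r0$mod_class, "canonical")
  expect_true(r0$templated)

  # the hand fixture: precursor AAAA CCCCGGGG TTTT, canonical CCCCGGGG
  p <- "AAAACCCCGGGGTTTT"
  t1 <- call_isomir("CCCCGGGGT", p, 4, 12, min_core = 8)
  expect_equal(t1$three_offset, 1L)
  expect_equal(t1$three_tail, "")
  expect_equal(t1$mod_class, "three_only")
  expect_true(t1$templated)

  t2 <- call_isomir("CCCCGGGGA", p, 4, 12, min_core = 8)
  expect_equal(t2$three_offset, 0L)
  expect_equal(t2$three_tail, "A")
  expect_equal(t2$mod_class, "three_only")
  expect_false(t2$templated)

  # 5' variants: templated upstream extension vs non-templated tail
  ext5 <- paste0(substr(g$precursor, g$start, g$start), g$mature)
  r5 <- call_isomir(ext5, g$precursor, g$start, g$end)
  expect_equal(r5$five_offset, -1L)
  expect_equal(r5$five_tail, "")
  expect_equal(r5$mod_class, "five_only")

  flank_base <- substr(g$precursor, g$start, g$start)
  other <- setdiff(c("A", "C", "G", "T"), flank_base)[1]
  nt5 <- paste0(other, g$mature)
  rn5 <- call_isomir(nt5, g$precursor, g$start, g$end)
  expect_equal(rn5$five_offset, 0L)
  expect_equal(rn5$five_tail, other)
  expect_false(rn5$templated)

  # deletion at the 5' end plus non-templated 3' tail: both ends modified
  del_base <- substr(g$precursor, g$end + 1, g$end + 1)
  tail3 <- setdiff(c("A", "C", "G", "T"), del_base)[1]
  q <- paste0(substr(g$mature, 3, nchar(g$mature)), tail3)
  rb <- call_isomir(q, g$precursor, g$start, g$end)
  expect_equal(rb$five_offset, 2L)
  expect_equal(rb$three_tail, tail3)
  expect_equal(rb$mod_class, "both")

  # reconstruction invariant for every record above
  cases <- list(
    list(r0, g$precursor, g$mature),
    list(t1, p, "CCCCGGGGT"),
    list(t2, p, "CCCCGGGGA"),
    list(r5, g$precursor, ext5),
    list(rn5, g$precursor, nt5),
    list(rb, g$precursor, q)
  )
  for (cs in cases) {
    r <- cs[[1]]
    expect_equal(
      paste0(
        r$five_tail,
        substr(cs[[2]], r$aligned_start + 1, r$aligned_end),
        r$three_tail
      ),
      cs[[3]]
    )
  }

  # too short / no core -> unassignable
  expect_null(call_isomir("ACGTACGTACGTACGTACGT", g$precursor, g$start, g$end))
})

test_that("templated 3' extension grows the offset one base at a time", {
  g <- demo_group()
  for (k in 0:4) {
    q <- substr(g$precursor, g$start + 1, g$end + k)
    r <- call_isomir(q, g$precursor, g$start, g$end)
    expect_equal(r$three_offset, k)
    expect_equal(r$five_tail, "")
    expect_equal(r$three_tail, "")
  }
})

test_that("build_groups pairs matures with containing precursors", {
  g <- demo_group()
  # two arms of one precursor: two matures, one group each
  arm5 <- substr(g$precursor, 2, 19)
  hairpin <- paste0(g$precursor, "GAATTCGGA")
  refs <- reference_records(
    record_id = c("m5", "m3", "pre"),
    species = "pig",
    rna_class = c("mirna_mature", "mirna_mature", "mirna_precursor"),
    tier = "known",
    sequence = c(arm5, g$mature, hairpin)
  )
  annot <- annotate_sequences(c(arm5, g$mature), refs)
  groups <- build_groups(annot, refs)
  expect_equal(nrow(groups), 2L)
  expect_setequal(groups$mature_id, c("m5", "m3"))
  expect_true(all(groups$precursor_id == "pre"))
  expect_equal(
    substr(
      groups$precursor_seq[groups$mature_id == "m3"],
      groups$mature_start[groups$mature_id == "m3"] + 1,
      groups$mature_end[groups$mature_id == "m3"]
    ),
    g$mature
  )

  # members attach to their own arm's group
  m3_members <- groups$members[[which(groups$mature_id == "m3")]]
  expect_true(g$mature %in% m3_members$query_seq)
})

test_that("a sequence hitting matures of two precursors is multi-mapped to both", {
  g <- demo_group()
  refs <- reference_records(
    record_id = c("mat", "preA", "preB"),
    species = "pig",
    rna_class = c("mirna_mature", "mirna_precursor", "mirna_precursor"),
    tier = "known",
    sequence = c(
      g$mature,
      g$precursor,
      paste0("TTGACCAGTC", g$mature, "ACCAGTAC")
    )
  )
  annot <- annotate_sequences(g$mature, refs)
  groups <- build_groups(annot, refs)
  expect_equal(nrow(groups), 2L)
  mem <- dplyr::bind_rows(groups$members)
  expect_equal(nrow(mem), 2L)
  expect_true(all(mem$multi_mapped))
})

test_that("a declared mature missing from its precursor is a reference-integrity error", {
  refs <- reference_records(
    record_id = c("mat", "pre"),
    species = "pig",
    rna_class = c("mirna_mature", "mirna_precursor"),
    tier = "known",
    sequence = c("TGAGGTAGTAGGTTGTATAGTT", random_seq_chr(60))
  )
  annot <- annotate_sequences("TGAGGTAGTAGGTTGTATAGTT", refs)
  expect_error(
    build_groups(annot, refs,
      pairs = tibble::tibble(mature_id = "mat", precursor_id = "pre")
    ),
    "reference integrity"
  )
})

test_that("ranks are dense, deterministic and order-invariant", {
  recs <- tibble::tibble(
    group_id = "g",
    query_seq = c("CCC", "AAA", "BBB", "DDD"),
    total_count = c(10L, 100L, 5L, 5L)
  )
  ranked <- rank_isomirs(recs)
  expect_equal(ranked$rank[match(c("AAA", "CCC", "BBB", "DDD"), ranked$query_seq)],
    c(1L, 2L, 3L, 4L)
  ) # tie 5/5 broken lexicographically: BBB before DDD
  shuffled <- rank_isomirs(recs[c(3, 1, 4, 2), ])
  expect_equal(
    ranked[order(ranked$query_seq), ],
    shuffled[order(shuffled$query_seq), ]
  )
})

test_that("call_isomirs + summarize_isomirs satisfy the partition invariants", {
  cfg <- sim_config(
    n_precursors = 30L, n_samples = 3L, reads_per_sample = 4000L, seed = 23L
  )
  sim <- simulate_srna(cfg)
  collapsed <- lapply(unique(sim$reads$sample_id), function(s) {
    sim$reads[sim$reads$sample_id == s, ] |>
      clip_adapter(min_len = 16L) |>
      trim_leading_n() |>
      collapse_reads(s)
  })
  tab <- join_samples(collapsed)
  annot <- annotate_sequences(tab$sequence, sim$refs)
  groups <- build_groups(annot, sim$refs)
  recs <- call_isomirs(groups, tab)
  expect_gt(nrow(recs), 0L)

  # reconstruction holds for every single record
  ginfo <- groups[match(recs$group_id, groups$group_id), ]
  rebuilt <- paste0(
    recs$five_tail,
    substr(ginfo$precursor_seq, recs$aligned_start + 1, recs$aligned_end),
    recs$three_tail
  )
  expect_equal(rebuilt, recs$query_seq)

  s <- summarize_isomirs(recs, groups)
  n_main <- sum(recs$precursor_available)
  expect_equal(sum(s$mod_class$n), n_main)
  expect_equal(s$totals$n_templated + s$totals$n_nontemplated, n_main)
  expect_equal(s$mature_only$n_records, sum(!recs$precursor_available))
  expect_equal(sum(s$per_group$n_isomirs), n_main)
  comp <- s$base_composition
  for (grp in split(comp, paste(comp$end, comp$change))) {
    if (sum(grp$n) > 0) expect_equal(sum(grp$fraction), 1, tolerance = 1e-9)
  }
  # canonical records carry zero offsets and empty tails
  can <- recs[recs$mod_class == "canonical", ]
  expect_true(all(can$five_offset == 0 & can$three_offset == 0))
  expect_true(all(can$five_tail == "" & can$three_tail == ""))
})

test_that("single canonical-only group ranks the canonical form first", {
  g <- demo_group()
  refs <- reference_records(
    record_id = c("mat", "pre"),
    species = "pig",
    rna_class = c("mirna_mature", "mirna_precursor"),
    tier = "known",
    sequence = c(g$mature, g$precursor)
  )
  annot <- annotate_sequences(g$mature, refs)
  groups <- build_groups(annot, refs)
  tab <- join_samples(list(collapse_reads(reads_tbl(rep(g$mature, 4)), "s1")))
  recs <- call_isomirs(groups, tab)
  s <- summarize_isomirs(recs, groups)
  expect_equal(s$mod_class$n[s$mod_class$mod_class == "canonical"], 1L)
  r1 <- s$rank1_by_canonical
  expect_equal(
    r1$n_groups[r1$canonical_present & r1$rank1_class == "canonical"], 1L
  )
})

test_that("aggregate_to_mirna conserves member reads and flags multi-mapping", {
  g <- demo_group()
  refs <- reference_records(
    record_id = c("mat", "pre"),
    species = "pig",
    rna_class = c("mirna_mature", "mirna_precursor"),
    tier = "known",
    sequence = c(g$mature, g$precursor)
  )
  variant <- substr(g$precursor, g$start, g$end) # 5' templated extension
  tab <- join_samples(list(
    collapse_reads(reads_tbl(c(rep(g$mature, 3), rep(variant, 4))), "s1"),
    collapse_reads(reads_tbl(rep(g$mature, 2)), "s2")
  ))
  annot <- annotate_sequences(tab$sequence, refs)
  groups <- build_groups(annot, refs)
  recs <- call_isomirs(groups, tab)
  agg <- aggregate_to_mirna(recs, tab)
  expect_equal(agg$s1, 7L)
  expect_equal(agg$s2, 2L)
  expect_false(agg$has_multimapped_members)

  # duplicated locus: shared member counted once per group, flagged
  refs2 <- reference_records(
    record_id = c("mat", "preA", "preB"),
    species = "pig",
    rna_class = c("mirna_mature", "mirna_precursor", "mirna_precursor"),
    tier = "known",
    sequence = c(g$mature, g$precursor, paste0("ACTGACTGAC", g$mature, "TTGCAATG"))
  )
  annot2 <- annotate_sequences(g$mature, refs2)
  groups2 <- build_groups(annot2, refs2)
  tab2 <- join_samples(list(collapse_reads(reads_tbl(rep(g$mature, 5)), "s1")))
  recs2 <- call_isomirs(groups2, tab2)
  agg2 <- aggregate_to_mirna(recs2, tab2)
  expect_equal(nrow(agg2), 2L)
  expect_equal(sum(agg2$s1), 10L) # documented double counting
  expect_true(all(agg2$has_multimapped_members))
})

test_that("mature-only groups report unknown templating, kept out of main counts", {
  mature <- "TGAGGTAGTAGGTTGTATAGTT"
  refs <- reference_records(
    "mat-only", "human", "mirna_mature", "orthologue", mature
  )
  variant <- paste0(substr(mature, 2, nchar(mature)), "") # 5' deletion
  annot <- annotate_sequences(c(mature, variant), refs)
  groups <- build_groups(annot, refs)
  expect_false(groups$precursor_available)
  tab <- join_samples(list(
    collapse_reads(reads_tbl(c(rep(mature, 3), variant)), "s1")
  ))
  recs <- call_isomirs(groups, tab)
  expect_true(all(is.na(recs$templated)))
  s <- summarize_isomirs(recs, groups)
  expect_equal(s$totals$n_isomirs, 0L)
  expect_equal(s$mature_only$n_records, nrow(recs))
})
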