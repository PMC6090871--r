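test_that("search_hits finds exact full-query occurrences with correct coordinates", {
  refs <- make_test_refs()
  pig_pre <- refs$sequence[refs$record_id == "ssc-mir-a-pre"]
  pig_mat <- refs$sequence[refs$record_id == "ssc-mir-a-mat"]

  hits <- search_hits(pig_mat, refs)
  h <- hits[hits$record_id == "ssc-mir-a-pre", ]
  expect_equal(nrow(h), 1L)
  expect_equal(
    substr(pig_pre, h$s_start + 1, h$s_end),
    pig_mat
  )
  expect_equal(h$q_start, 0L)
  expect_equal(h$q_end, nchar(pig_mat))

  # a query occurring twice in one reference yields two hits
  q2 <- "ACGTTGCAACGTTGCAA"
  ref2 <- reference_records(
    "dup", "pig", "mrna", "known", paste0(q2, "TTTT", q2)
  )
  h2 <- search_hits(q2, ref2)
  h2 <- h2[h2$strand == "+", ]
  expect_equal(sort(h2$s_start), c(0L, nchar(q2) + 4L))

  # one mismatch kills the hit entirely
  mm <- paste0(substr(pig_mat, 1, nchar(pig_mat) - 1), "A")
  expect_false(identical(mm, pig_mat))
  expect_equal(nrow(search_hits(mm, refs)), 0L)

  # N is not a wildcard and never matches; bad letters are an error
  withN <- paste0("N", substr(pig_mat, 2, nchar(pig_mat)))
  expect_equal(nrow(search_hits(withN, refs)), 0L)
  expect_error(search_hits("ACGTX", refs), "only A, C, G, T or N")
})

test_that("search_hits agrees exactly with the naive substring-scan oracle", {
  withr::with_seed(60, {
    for (case in 1:30) {
      n_ref <- sample(3:8, 1)
      refs <- reference_records(
        record_id = paste0("ref", seq_len(n_ref)),
        species = sample(c("pig", "human", "cattle"), n_ref, replace = TRUE),
        rna_class = sample(
          c("mirna_mature", "mirna_precursor", "trna", "rrna",
            "pirna_cluster", "mrna", "other_ncrna"),
          n_ref,
          replace = TRUE
        ),
        tier = "known",
        sequence = vapply(sample(50:300, n_ref, replace = TRUE), random_seq_chr, "")
      )
      refs$tier[refs$species != "pig"] <- "orthologue"
      # queries: planted substrings plus random never-seen ones
      planted <- vapply(1:5, function(i) {
        r <- sample(n_ref, 1)
        len <- sample(16:30, 1)
        at <- sample(nchar(refs$sequence[r]) - len, 1)
        substr(refs$sequence[r], at, at + len - 1)
      }, "")
      random_qs <- vapply(rep(17, 5), random_seq_chr, "")
      queries <- unique(c(planted, random_qs))
      expect_equal(
        sort_hits(search_hits(queries, refs)),
        sort_hits(naive_search(queries, refs))
      )
    }
  })
})

test_that("minus-strand matching applies only to genomic-context classes", {
  q <- "ACCGGTTAACCGGTTAAGGT"
  rc <- revcomp_chr(q)
  refs <- reference_records(
    record_id = c("pir", "mat"),
    species = "pig",
    rna_class = c("pirna_cluster", "mirna_mature"),
    tier = "known",
    sequence = c(paste0("GGGG", rc, "AAAA"), rc)
  )
  hits <- search_hits(q, refs)
  expect_equal(hits$record_id, "pir")
  expect_equal(hits$strand, "-")
  expect_equal(hits$s_start, 4L)
  expect_equal(hits$s_end, 4L + nchar(q))
})

test_that("resolve_hits applies exclusion first, then class priority and precedence", {
  refs <- make_test_refs()
  pig_mat <- refs$sequence[refs$record_id == "ssc-mir-a-mat"]
  cow_mat <- refs$sequence[refs$record_id == "bta-mir-c-mat"]
  hum_mat <- refs$sequence[refs$record_id == "hsa-mir-d-mat"]
  pred_mat <- refs$sequence[refs$record_id == "ssc-pred-b-mat"]
  annot <- annotate_sequences(
    c(pig_mat, cow_mat, hum_mat, pred_mat, "ACGTACGTACGTACGTAGGG"), refs
  )

  # pig mature also planted in the human rRNA -> excluded from miRNAs
  a_pig <- annot[annot$query_seq == pig_mat, ]
  expect_equal(a_pig$excluded_as, "rrna_hit")
  expect_equal(a_pig$rna_class, "rrna")
  expect_equal(nrow(a_pig$mirna_assignments[[1]]), 0L)

  # cattle mature also planted in a pig tRNA -> excluded as trna_hit
  a_cow <- annot[annot$query_seq == cow_mat, ]
  expect_equal(a_cow$excluded_as, "trna_hit")
  expect_equal(a_cow$rna_class, "trna")

  # human-only mature stays a miRNA, novel for the pig, but its presence
  # inside a pig precursor is retained in the assignments
  a_hum <- annot[annot$query_seq == hum_mat, ]
  expect_equal(a_hum$rna_class, "mirna_mature")
  expect_equal(a_hum$species, "human")
  expect_equal(a_hum$tier, "orthologue")
  expect_true("ssc-mir-e-pre" %in% a_hum$mirna_assignments[[1]]$record_id)

  # pig predicted mature
  a_pred <- annot[annot$query_seq == pred_mat, ]
  expect_equal(a_pred$rna_class, "mirna_mature")
  expect_equal(a_pred$tier, "predicted")

  # unannotated bucket
  expect_equal(
    annot$rna_class[annot$query_seq == "ACGTACGTACGTACGTAGGG"], "unannotated"
  )
})

test_that("species/tier precedence prefers pig-known over orthologues", {
  shared <- "TAGCTTATCAGACTGATGTTGA"
  refs <- reference_records(
    record_id = c("ssc-m", "bta-m", "hsa-m"),
    species = c("pig", "cattle", "human"),
    rna_class = "mirna_mature",
    tier = c("known", "orthologue", "orthologue"),
    sequence = shared
  )
  a <- annotate_sequences(shared, refs)
  expect_equal(a$species, "pig")
  expect_equal(a$tier, "known")
  expect_equal(nrow(a$mirna_assignments[[1]]), 3L)

  # resolve is independent of hit order
  hits <- search_hits(shared, refs)
  r1 <- resolve_hits(shared, hits, refs)
  r2 <- resolve_hits(shared, hits[rev(seq_len(nrow(hits))), ], refs)
  expect_equal(r1, r2)
})

test_that("queries shorter than 16 nt are never annotated", {
  refs <- make_test_refs()
  short <- substr(refs$sequence[refs$record_id == "ssc-mir-a-mat"], 1, 12)
  a <- annotate_sequences(short, refs)
  expect_equal(a$rna_class, "unannotated")
})

test_that("no miRNA-labelled sequence survives with a contaminant hit (re-search)", {
  cfg <- sim_config(
    n_precursors = 30L, n_samples = 2L, reads_per_sample = 3000L, seed = 77L
  )
  sim <- simulate_srna(cfg)
  seqs <- unique(sim$truth$insert)
  annot <- annotate_sequences(seqs, sim$refs)
  mir <- annot$query_seq[annot$rna_class %in% c("mirna_mature", "mirna_precursor")]
  excl <- sim$refs$sequence[
    (sim$refs$rna_class == "trna" & sim$refs$species == "pig") |
      (sim$refs$rna_class == "rrna" & sim$refs$species %in% c("pig", "human"))
  ]
  offenders <- vapply(mir, function(q) any(grepl(q, excl, fixed = TRUE)), TRUE)
  expect_equal(sum(offenders), 0L)
})

test_that("summarize_classes partitions 100% over classes for both weightings", {
  cfg <- sim_config(
    n_precursors = 25L, n_samples = 3L, reads_per_sample = 3000L, seed = 13L
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
  cs <- summarize_classes(annot, tab)
  expect_s3_class(cs, "class_summary")
  expect_equal(sum(cs$overall$pct_unique), 100, tolerance = 1e-9)
  expect_equal(sum(cs$overall$pct_reads), 100, tolerance = 1e-9)
  per <- split(cs$per_sample$pct_reads, cs$per_sample$sample_id)
  for (p in per) expect_equal(sum(p), 100, tolerance = 1e-9)

  # single-class case
  one <- annotate_sequences("TGAGGTAGTAGGTTGTATAGTT", reference_records(
    "m", "pig", "mirna_mature", "known", "TGAGGTAGTAGGTTGTATAGTT"
  ))
  tab1 <- join_samples(list(
    collapse_reads(reads_tbl(rep("TGAGGTAGTAGGTTGTATAGTT", 3)), "s1")
  ))
  cs1 <- summarize_classes(one, tab1)
  expect_equal(cs1$overall$rna_class, "mirna")
  expect_equal(cs1$overall$pct_unique, 100)
  expect_equal(cs1$overall$pct_reads, 100)
})

test_that("class read proportions recover the generator contaminant mix", {
  cfg <- sim_config(
    n_precursors = 40L, n_samples = 4L, reads_per_sample = 6000L,
    nb_size = 50, seed = 14L
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
  cs <- summarize_classes(annot, tab)
  got <- cs$overall
  # unannotated bucket holds the non-templated isomiRs; everything else
  # should recover the configured read fractions to within a few percent
  for (cl in c("rrna", "trna", "other_ncrna")) {
    expect_lt(
      abs(got$pct_reads[got$rna_class == cl] / 100 -
        cfg$contaminant_fractions[[cl]]),
      0.05
    )
  }
})

test_that("novelty_breakdown counts origins and novel matures on known precursors", {
  refs <- make_test_refs()
  hum_mat <- refs$sequence[refs$record_id == "hsa-mir-d-mat"]
  pred_mat <- refs$sequence[refs$record_id == "ssc-pred-b-mat"]
  annot <- annotate_sequences(c(hum_mat, pred_mat), refs)
  nb <- novelty_breakdown(annot)
  bo <- nb$by_origin
  expect_equal(bo$n_sequences[bo$origin == "human-orthologue"], 1L)
  expect_equal(bo$n_sequences[bo$origin == "pig-predicted"], 1L)
  expect_equal(sum(bo$n_sequences), 2L)
  expect_equal(nb$n_mature_mirnas, 2L)
  # the human mature sits inside a pig precursor
  expect_equal(nb$novel_mature_known_precursor, 1L)

  # all-pig case
  pig_only <- reference_records(
    "p1", "pig", "mirna_mature", "known", "TGAGGTAGTAGGTTGTATAGTT"
  )
  nb2 <- novelty_breakdown(annotate_sequences("TGAGGTAGTAGGTTGTATAGTT", pig_only))
  expect_equal(
    nb2$by_origin$n_sequences[nb2$by_origin$origin == "pig-known"], 1L
  )
  expect_equal(sum(nb2$by_origin$n_sequences), 1L)
})

test_that("reference FASTA + manifest round trip", {
  refs <- make_test_refs()
  fa <- withr::local_tempfile(fileext = ".fasta")
  mf <- withr::local_tempfile(fileext = ".tsv")
  write_reference_fasta(refs, fa, mf)
  back <- read_reference_fasta(fa, mf)
  expect_equal(as.data.frame(back), as.data.frame(refs))
  expect_error(
    reference_records("x", "pig", "mirna_mature", "orthologue", "ACGT"),
    "orthologue"
  )
})
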