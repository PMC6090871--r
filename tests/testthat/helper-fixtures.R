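# Shared fixtures, built in code.

reads_tbl <- function(seqs, ids = NULL) {
  tibble::tibble(
    read_id = ids %||% paste0("r", seq_along(seqs)),
    sequence = seqs,
    quality = strrep("I", nchar(seqs))
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# small handcrafted multi-species reference collection:
#  - one pig known mature+precursor, one pig predicted, one cattle, one human
#  - the human mature lies inside a pig precursor (novel mature, known gene)
#  - one mature planted inside a pig tRNA and one inside a human rRNA
make_test_refs <- function(seed = 101) {
  withr::with_seed(seed, {
    flank <- function(n) random_seq_chr(n)
    pig_mat <- "TGAGGTAGTAGGTTGTATAGTT"
    pig_pre <- paste0(flank(15), pig_mat, flank(20))
    pred_mat <- "ACCGTAAGCTTGACCGTATGCA"
    pred_pre <- paste0(flank(12), pred_mat, flank(18))
    cow_mat <- "TTCACAGTGGCTAAGTTCTGC"
    cow_pre <- paste0(flank(14), cow_mat, flank(16))
    hum_mat <- "CAAAGTGCTTACAGTGCAGGTAG"
    hum_pre <- paste0(flank(11), hum_mat, flank(19))
    # human mature also sits inside a pig precursor (no pig mature for it)
    pigpre_hosting <- paste0(flank(13), hum_mat, flank(17))
    trna_planted <- "GTTTCCGTAGTGTAGTGGTTATCACGTTCGCCT"
    rrna_host <- paste0(flank(200), pig_mat, flank(180))
    trna_host <- paste0(flank(20), cow_mat, flank(25))

    srnakit::reference_records(
      record_id = c(
        "ssc-mir-a-mat", "ssc-mir-a-pre",
        "ssc-pred-b-mat", "ssc-pred-b-pre",
        "bta-mir-c-mat", "bta-mir-c-pre",
        "hsa-mir-d-mat", "hsa-mir-d-pre",
        "ssc-mir-e-pre",
        "ssc-trna-1", "ssc-trna-2",
        "hsa-rrna-1",
        "ssc-pirna-1", "ssc-mrna-1", "ssc-ncrna-1"
      ),
      species = c(
        "pig", "pig", "pig", "pig", "cattle", "cattle", "human", "human",
        "pig", "pig", "pig", "human", "pig", "pig", "pig"
      ),
      rna_class = c(
        "mirna_mature", "mirna_precursor",
        "mirna_mature", "mirna_precursor",
        "mirna_mature", "mirna_precursor",
        "mirna_mature", "mirna_precursor",
        "mirna_precursor",
        "trna", "trna", "rrna",
        "pirna_cluster", "mrna", "other_ncrna"
      ),
      tier = c(
        "known", "known", "predicted", "predicted",
        "orthologue", "orthologue", "orthologue", "orthologue",
        "known",
        "known", "known", "known", "known", "known", "known"
      ),
      sequence = c(
        pig_mat, pig_pre, pred_mat, pred_pre, cow_mat, cow_pre,
        hum_mat, hum_pre, pigpre_hosting,
        trna_planted, trna_host, rrna_host,
        random_seq_chr(400), random_seq_chr(600), random_seq_chr(150)
      )
    )
  })
}

# cached default-scale simulation + pipeline run shared by the acceptance
# criteria (the standard calibration: 200 groups, ~1e5 reads)
.accept_cache <- new.env(parent = emptyenv())

acceptance_run <- function() {
  if (is.null(.accept_cache$rep)) {
    .accept_cache$cfg <- srnakit::sim_config(seed = 1L)
    .accept_cache$rep <- srnakit::end_to_end_check(.accept_cache$cfg)
  }
  list(cfg = .accept_cache$cfg, rep = .accept_cache$rep)
}
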