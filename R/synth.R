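#' Configuration for the synthetic small RNA library generator
#'
#' Defaults describe the library structure this generator emulates: a
#' deeply sequenced small RNA experiment in a species with incomplete
#' annotation. Modification-class probabilities (3'-only 0.54, both 0.29,
#' 5'-only 0.10, canonical 0.07), the 15% leading-N artifact, the 126 nt
#' read length, the Illumina Universal Adapter, mature lengths 16-27 nt
#' peaking at 23, and an A-biased non-templated tail alphabet
#' (A 0.35 / C 0.20 / G 0.20 / T 0.25) are fixed properties of that world;
#' the simulation scale (200 precursors, 4 samples x 25000 reads) is the
#' desk-scale calibration used throughout the test suite.
#'
#' @param n_precursors Number of miRNA precursor loci (groups).
#' @param precursor_len Length range of precursors (nt).
#' @param mature_len Range of canonical mature lengths (nt).
#' @param mature_len_peak,mature_len_sd Peak and spread of the discrete
#'   mature length distribution.
#' @param n_samples Number of libraries.
#' @param reads_per_sample Expected reads per library.
#' @param mod_class_probs Probabilities over
#'   `canonical`/`five_only`/`three_only`/`both` for miRNA reads.
#' @param templated_prob Per-end probability that an end *addition* is
#'   templated (drawn from the precursor flank) rather than a
#'   non-templated tail.
#' @param add_prob Per-end probability that a modification is an addition
#'   (vs a deletion).
#' @param offset_probs Probabilities of offset magnitudes 1, 2, ... nt.
#' @param tail_base_probs Base probabilities for non-templated tails.
#' @param tail_len_geom_p,tail_len_max Truncated-geometric tail length
#'   distribution (support 1..`tail_len_max`).
#' @param contaminant_fractions Read fractions for
#'   rrna/trna/pirna_cluster/mrna/other_ncrna; the remainder is miRNA.
#' @param species_probs Species mix of the simulated miRNA loci (the
#'   non-pig ones are annotated via orthologues).
#' @param p_mature_only Fraction of miRNA loci with a mature but no
#'   precursor reference available.
#' @param n_planted_trna,n_planted_rrna Number of mature miRNA sequences
#'   additionally embedded verbatim into tRNA / rRNA references (planted
#'   false-miRNA cases for the exclusion rule).
#' @param p_leadN Probability of a prepended leading `N` (HiSeq 4000
#'   first-cycle artifact).
#' @param adapter 3' adapter sequence appended to every insert.
#' @param read_len Fixed raw read length.
#' @param nb_size Negative-binomial size (dispersion) for per-sample
#'   counts.
#' @param abundance_exponent Power-law exponent of the group abundance
#'   distribution (1.2 gives a dominant miRNA near 22% of miRNA reads).
#' @param seed Optional integer seed; given the seed, output is
#'   reproducible byte-for-byte.
#'
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_precursors = 200L,
                       precursor_len = c(70L, 90L),
                       mature_len = c(16L, 27L),
                       mature_len_peak = 23,
                       mature_len_sd = 1.5,
                       n_samples = 4L,
                       reads_per_sample = 25000L,
                       mod_class_probs = c(
                         canonical = 0.07, five_only = 0.10,
                         three_only = 0.54, both = 0.29
                       ),
                       templated_prob = c(five = 0.54, three = 0.37),
                       add_prob = c(five = 0.5, three = 0.75),
                       offset_probs = c(0.7, 0.3),
                       tail_base_probs = c(A = 0.35, C = 0.20, G = 0.20, T = 0.25),
                       tail_len_geom_p = 0.6,
                       tail_len_max = 4L,
                       contaminant_fractions = c(
                         rrna = 0.70, trna = 0.10, pirna_cluster = 0.005,
                         mrna = 0.005, other_ncrna = 0.06
                       ),
                       species_probs = c(pig = 0.60, cattle = 0.15, human = 0.25),
                       p_mature_only = 0.05,
                       n_planted_trna = 2L,
                       n_planted_rrna = 4L,
                       p_leadN = 0.15,
                       adapter = srna_adapter,
                       read_len = 126L,
                       nb_size = 5,
                       abundance_exponent = 1.2,
                       seed = NULL) {
  cfg <- as.list(environment())
  chk_probs <- function(p, what) {
    if (abs(sum(p) - 1) > 1e-8 || any(p < 0)) {
      abort(paste0(what, " must be non-negative and sum to 1"))
    }
  }
  chk_probs(cfg$mod_class_probs[c("canonical", "five_only", "three_only", "both")],
    "mod_class_probs"
  )
  chk_probs(cfg$tail_base_probs[c("A", "C", "G", "T")], "tail_base_probs")
  chk_probs(cfg$species_probs, "species_probs")
  if (sum(cfg$contaminant_fractions) >= 1) {
    abort("contaminant_fractions must sum to < 1 (remainder is miRNA)")
  }
  margin <- length(cfg$offset_probs) + cfg$tail_len_max
  if (cfg$precursor_len[1] < cfg$mature_len[2] + 2L * margin) {
    abort(paste0(
      "infeasible config: mature window plus maximal offsets/tails (",
      cfg$mature_len[2] + 2L * margin,
      " nt) exceeds the shortest precursor (", cfg$precursor_len[1], " nt)"
    ))
  }
  structure(cfg, class = "sim_config")
}

BASES <- c("A", "C", "G", "T")

random_seqs <- function(n, lens) {
  chars <- sample(BASES, sum(lens), replace = TRUE)
  vapply(
    split(chars, rep.int(seq_len(n), lens)),
    paste0,
    character(1),
    collapse = ""
  ) |> unname()
}

sample_int <- function(range) sample(range[1]:range[2], 1L)

#' Simulate a small RNA sequencing experiment with full ground truth
#'
#' Generates a multi-sample small RNA library: precursor-derived isomiR
#' reads with controlled templated/non-templated 5'/3' modifications,
#' rRNA/tRNA/piRNA/mRNA/ncRNA fragment contamination at configured
#' proportions, 3' adapter read-through, a configurable fraction of reads
#' carrying a prepended leading `N`, and per-sample counts with
#' negative-binomial overdispersion. Every read carries a truth label
#' that reconstructs its pre-adapter, pre-N insert exactly.
#'
#' Non-templated tail bases are sampled conditional on differing from the
#' precursor's templated base at that position, so the truth labels are
#' unambiguous. Selected mature sequences can be planted verbatim inside
#' tRNA/rRNA references to create the miRNA/contaminant dual-hit cases
#' the exclusion rule must catch.
#'
#' @param cfg A [sim_config()].
#' @return An `srna_sim` list: `reads` (tibble `sample_id`, `read_id`,
#'   `sequence`, `quality`), `refs` (a `reference_records` tibble),
#'   `truth` (per-read tibble: `read_id`, `sample_id`, `record_id`,
#'   `rna_class`, `group_id`, `five_offset`, `three_offset`, `five_tail`,
#'   `three_tail`, `insert`, `lead_n`), `planted` (tibble of planted
#'   mature/contaminant pairs), `config`.
#' @export
simulate_srna <- function(cfg = sim_config()) {
  if (!inherits(cfg, "sim_config")) abort("cfg must come from sim_config()")
  runner <- function() .simulate_srna_impl(cfg)
  if (!is.null(cfg$seed)) withr::with_seed(cfg$seed, runner()) else runner()
}

.simulate_srna_impl <- function(cfg) {
  n_pre <- cfg$n_precursors
  margin <- length(cfg$offset_probs) + cfg$tail_len_max

  ## --- miRNA loci -----------------------------------------------------
  plens <- sample(cfg$precursor_len[1]:cfg$precursor_len[2], n_pre, replace = TRUE)
  mlen_support <- cfg$mature_len[1]:cfg$mature_len[2]
  mlen_w <- stats::dnorm(mlen_support, cfg$mature_len_peak, cfg$mature_len_sd)
  mlens <- sample(mlen_support, n_pre, replace = TRUE, prob = mlen_w)
  pre_seqs <- random_seqs(n_pre, plens)
  mstarts <- vapply(seq_len(n_pre), function(i) {
    sample(margin:(plens[i] - mlens[i] - margin), 1L)
  }, integer(1))
  species <- sample(names(cfg$species_probs), n_pre,
    replace = TRUE, prob = cfg$species_probs
  )
  tier <- ifelse(species == "pig", "known", "orthologue")
  mature_only <- runif(n_pre) < cfg$p_mature_only
  mat_id <- sprintf("mir-%03d-mat", seq_len(n_pre))
  pre_id <- sprintf("mir-%03d-pre", seq_len(n_pre))
  mat_seq <- substr(pre_seqs, mstarts + 1L, mstarts + mlens)

  loci <- tibble(
    idx = seq_len(n_pre), mature_id = mat_id, precursor_id = pre_id,
    species = species, tier = tier,
    precursor_seq = pre_seqs, mature_seq = mat_seq,
    mature_start = mstarts, mature_end = mstarts + mlens,
    mature_only = mature_only,
    group_id = ifelse(mature_only,
      paste0(mat_id, "|mature-only"), paste0(pre_id, "|", mat_id)
    )
  )

  ## --- contaminant references ----------------------------------------
  contam <- bind_rows(
    tibble(
      record_id = sprintf("rrna-%02d", 1:4), rna_class = "rrna",
      species = c("pig", "human", "pig", "human"),
      sequence = random_seqs(4L, sample(1500:5000, 4L))
    ),
    tibble(
      record_id = sprintf("trna-%02d", 1:20), rna_class = "trna",
      species = "pig",
      sequence = random_seqs(20L, sample(70:90, 20L, replace = TRUE))
    ),
    tibble(
      record_id = sprintf("pirna-%02d", 1:2), rna_class = "pirna_cluster",
      species = "pig",
      sequence = random_seqs(2L, sample(800:1200, 2L))
    ),
    tibble(
      record_id = sprintf("mrna-%02d", 1:5), rna_class = "mrna",
      species = "pig",
      sequence = random_seqs(5L, sample(500:2000, 5L))
    ),
    tibble(
      record_id = sprintf("ncrna-%02d", 1:10), rna_class = "other_ncrna",
      species = "pig",
      sequence = random_seqs(10L, sample(100:500, 10L, replace = TRUE))
    )
  ) |> mutate(tier = "known")

  ## --- plant mature sequences inside tRNA / rRNA ----------------------
  plant <- function(contam, class, n_plant) {
    if (n_plant < 1L) return(list(contam = contam, planted = NULL))
    avail <- which(contam$rna_class == class)
    if (n_plant > length(avail)) {
      abort(paste0(
        "cannot plant ", n_plant, " matures into ", length(avail),
        " ", class, " references"
      ))
    }
    hosts <- avail[seq_len(n_plant)]
    donors <- sample(which(!loci$mature_only), n_plant)
    for (k in seq_len(n_plant)) {
      host <- hosts[k]
      ins <- loci$mature_seq[donors[k]]
      at <- sample(seq_len(nchar(contam$sequence[host]) - nchar(ins) + 1L), 1L)
      substr(contam$sequence[host], at, at + nchar(ins) - 1L) <- ins
    }
    list(
      contam = contam,
      planted = tibble(
        mature_id = loci$mature_id[donors],
        mature_seq = loci$mature_seq[donors],
        contaminant_record = contam$record_id[hosts],
        contaminant_class = class
      )
    )
  }
  pt <- plant(contam, "trna", cfg$n_planted_trna)
  pr <- plant(pt$contam, "rrna", cfg$n_planted_rrna)
  contam <- pr$contam
  planted <- bind_rows(pt$planted, pr$planted)

  refs <- reference_records(
    record_id = c(
      loci$mature_id, loci$precursor_id[!loci$mature_only], contam$record_id
    ),
    species = c(
      loci$species, loci$species[!loci$mature_only], contam$species
    ),
    rna_class = c(
      rep("mirna_mature", n_pre),
      rep("mirna_precursor", sum(!loci$mature_only)),
      contam$rna_class
    ),
    tier = c(loci$tier, loci$tier[!loci$mature_only], contam$tier),
    sequence = c(
      loci$mature_seq, loci$precursor_seq[!loci$mature_only], contam$sequence
    )
  )

  ## --- abundances and per-sample counts --------------------------------
  w <- (1 / seq_len(n_pre)^cfg$abundance_exponent)
  w <- sample(w / sum(w)) # shuffle rank over loci
  f_mir <- 1 - sum(cfg$contaminant_fractions)
  sample_ids <- sprintf("s%02d", seq_len(cfg$n_samples))

  mod_levels <- c("canonical", "five_only", "three_only", "both")
  tail_len_probs <- cfg$tail_len_geom_p *
    (1 - cfg$tail_len_geom_p)^(seq_len(cfg$tail_len_max) - 1L)
  tail_len_probs <- tail_len_probs / sum(tail_len_probs)

  draw_tail <- function(len, templ_bases) {
    # templ_bases: precursor bases at the tail positions ("" when absent);
    # each tail base is sampled to differ from its templated base
    out <- character(len)
    for (j in seq_len(len)) {
      p <- cfg$tail_base_probs
      if (nzchar(templ_bases[j])) p[templ_bases[j]] <- 0
      out[j] <- sample(BASES, 1L, prob = p)
    }
    paste0(out, collapse = "")
  }

  make_mirna_insert <- function(g, mod) {
    ms <- loci$mature_start[g]
    me <- loci$mature_end[g]
    pseq <- loci$precursor_seq[g]
    m_only <- loci$mature_only[g]
    if (m_only) {
      pseq <- loci$mature_seq[g]
      ms <- 0L
      me <- nchar(pseq)
    }
    start <- ms
    end <- me
    five_tail <- ""
    three_tail <- ""

    mod_end <- function(end_name) {
      is_add <- runif(1) < cfg$add_prob[[end_name]]
      k <- sample(seq_along(cfg$offset_probs), 1L, prob = cfg$offset_probs)
      if (!is_add) {
        # deletion; keep a >=16 nt core so the variant stays callable
        k <- min(k, (end - start) - 16L)
        if (k < 1L) is_add <- TRUE
      }
      if (!is_add) {
        if (end_name == "five") start <<- start + k else end <<- end - k
        return(invisible())
      }
      templated <- !m_only && runif(1) < cfg$templated_prob[[end_name]]
      if (templated) {
        if (end_name == "five") start <<- start - k else end <<- end + k
      } else {
        t_len <- sample(seq_len(cfg$tail_len_max), 1L, prob = tail_len_probs)
        if (end_name == "five") {
          pos <- start - seq_len(t_len) # adjacent flank positions, outward
          tb <- if (m_only) rep("", t_len) else substring(pseq, pos + 1L, pos + 1L)
          bases <- draw_tail(t_len, tb)
          # bases were drawn outward; the tail string reads 5'->3'
          five_tail <<- paste(rev(strsplit(bases, "")[[1]]), collapse = "")
        } else {
          pos <- end + seq_len(t_len) - 1L
          tb <- if (m_only) rep("", t_len) else substring(pseq, pos + 1L, pos + 1L)
          three_tail <<- draw_tail(t_len, tb)
        }
      }
      invisible()
    }
    if (mod %in% c("five_only", "both")) mod_end("five")
    if (mod %in% c("three_only", "both")) mod_end("three")

    list(
      insert = paste0(five_tail, substr(pseq, start + 1L, end), three_tail),
      five_offset = start - ms,
      three_offset = end - me,
      five_tail = five_tail,
      three_tail = three_tail
    )
  }

  truth_list <- list()
  for (s in sample_ids) {
    # miRNA reads: per-locus negative-binomial counts
    mu_g <- w * f_mir * cfg$reads_per_sample
    n_g <- rnbinom(n_pre, size = cfg$nb_size, mu = mu_g)
    gi <- rep.int(seq_len(n_pre), n_g)
    if (length(gi)) {
      mods <- sample(mod_levels, length(gi),
        replace = TRUE, prob = cfg$mod_class_probs[mod_levels]
      )
      vs <- lapply(seq_along(gi), function(j) make_mirna_insert(gi[j], mods[j]))
      mir_rows <- tibble(
        record_id = loci$mature_id[gi],
        rna_class = "mirna",
        group_id = loci$group_id[gi],
        five_offset = vapply(vs, function(v) as.integer(v$five_offset), integer(1)),
        three_offset = vapply(vs, function(v) as.integer(v$three_offset), integer(1)),
        five_tail = vapply(vs, `[[`, character(1), "five_tail"),
        three_tail = vapply(vs, `[[`, character(1), "three_tail"),
        insert = vapply(vs, `[[`, character(1), "insert")
      )
    } else {
      mir_rows <- NULL
    }
    # contaminant reads: random 16-100 nt fragments of class references
    contam_rows <- purrr::map_dfr(names(cfg$contaminant_fractions), function(cl) {
      idx <- which(contam$rna_class == cl)
      mu <- cfg$contaminant_fractions[[cl]] * cfg$reads_per_sample / length(idx)
      n_r <- rnbinom(length(idx), size = cfg$nb_size, mu = mu)
      ri <- rep.int(idx, n_r)
      if (!length(ri)) return(NULL)
      reflen <- nchar(contam$sequence[ri])
      flen <- pmin(sample(16:100, length(ri), replace = TRUE), reflen)
      fstart <- floor(runif(length(ri)) * (reflen - flen + 1)) + 1L
      tibble(
        record_id = contam$record_id[ri],
        rna_class = cl,
        group_id = NA_character_,
        five_offset = NA_integer_, three_offset = NA_integer_,
        five_tail = NA_character_, three_tail = NA_character_,
        insert = substr(contam$sequence[ri], fstart, fstart + flen - 1L)
      )
    })
    rows <- bind_rows(mir_rows, contam_rows)
    if (!nrow(rows)) next
    rows <- rows[sample.int(nrow(rows)), , drop = FALSE]
    rows$sample_id <- s
    rows$read_id <- sprintf("%s:r%06d", s, seq_len(nrow(rows)))
    rows$lead_n <- runif(nrow(rows)) < cfg$p_leadN
    truth_list[[s]] <- rows
  }
  truth <- bind_rows(truth_list)

  ## --- assemble raw reads ---------------------------------------------
  body <- paste0(ifelse(truth$lead_n, "N", ""), truth$insert, cfg$adapter)
  fill_len <- pmax(cfg$read_len - nchar(body), 0L)
  fills <- character(nrow(truth))
  need <- which(fill_len > 0L)
  if (length(need)) {
    fills[need] <- random_seqs(length(need), fill_len[need])
  }
  seqs <- substr(paste0(body, fills), 1L, cfg$read_len)
  reads <- tibble(
    sample_id = truth$sample_id,
    read_id = truth$read_id,
    sequence = seqs,
    quality = strrep("I", nchar(seqs))
  )

  structure(
    list(
      reads = reads,
      refs = refs,
      truth = truth[c(
        "read_id", "sample_id", "record_id", "rna_class", "group_id",
        "five_offset", "three_offset", "five_tail", "three_tail",
        "insert", "lead_n"
      )],
      planted = if (nrow(planted)) planted else tibble(
        mature_id = character(), mature_seq = character(),
        contaminant_record = character(), contaminant_class = character()
      ),
      config = cfg
    ),
    class = "srna_sim"
  )
}

#' Write a simulated experiment to standard files
#'
#' Emits one gzip FASTQ per sample, the reference FASTA plus manifest
#' TSV, and the per-read truth table TSV.
#'
#' @param sim An `srna_sim` from [simulate_srna()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_sim <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (s in unique(sim$reads$sample_id)) {
    write_fastq(
      sim$reads[sim$reads$sample_id == s, c("read_id", "sequence", "quality")],
      file.path(dir, paste0(s, ".fastq.gz"))
    )
  }
  write_reference_fasta(
    sim$refs, file.path(dir, "refs.fasta"), file.path(dir, "manifest.tsv")
  )
  readr::write_tsv(sim$truth, file.path(dir, "truth.tsv"))
  invisible(dir)
}
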