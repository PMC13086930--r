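#' Synthetic cohort design
#'
#' Parameters of the synthetic benchmark cohort. The generator emulates the
#' structure the analysis assumes: two timepoints per subject with a
#' persistent private peptide core (high paired cosine similarity),
#' heavy-tailed log-normal background counts, planted gapped motifs whose
#' carrier peptides are enriched in one group, and serostatus loosely linked
#' to planted-motif carriage.
#'
#' @param n_case_subjects,n_control_subjects,n_qc_subjects subjects in the
#'   case, control and technical-control groups.
#' @param peptides_per_sample distinct peptides per sample.
#' @param background_log_mean,background_log_sd meanlog/sdlog of the
#'   log-normal background count distribution (rounded, truncated at 1).
#' @param n_planted_motifs number of planted gapped motifs.
#' @param planted_effect multiplicative count shift for planted peptides in
#'   carriers of the enriched group.
#' @param subject_core_fraction fraction of a subject's peptides shared
#'   between T1 and T2.
#' @param planted_reverse_fraction fraction of planted motifs enriched in
#'   controls instead of cases.
#' @param sero_link_strength probability that a carrier of a planted motif is
#'   scored seropositive for the matching mock virus.
#' @param carrier_prob_enriched,carrier_prob_other probability that a subject
#'   of the enriched (resp. other) group carries peptides matching a planted
#'   motif.
#' @param planted_peptides_per_motif distinct motif-matching peptides per
#'   carrier subject.
#' @param timepoint_noise_sd sdlog of the multiplicative noise applied to a
#'   subject's persistent counts at T2.
#' @param n_decoy_epitopes,n_autoantigen_decoys decoy reference records
#'   (random 9-25-mers) in the pathogen and autoantigen passes.
#' @param shared_peptides number of "public" library peptides present in
#'   every sample (with independent per-subject counts, persistent across
#'   timepoints); these produce the small positive unpaired similarity
#'   background seen in real cohorts.
#' @param sero_background_rate seropositivity probability for non-carriers.
#' @param rng_seed generation seed.
#' @return list of class `mimo_design`.
#' @export
cohort_design <- function(n_case_subjects = 20L,
                          n_control_subjects = 20L,
                          n_qc_subjects = 4L,
                          peptides_per_sample = 1000L,
                          background_log_mean = 3,
                          background_log_sd = 1.5,
                          n_planted_motifs = 4L,
                          planted_effect = 8,
                          subject_core_fraction = 0.8,
                          planted_reverse_fraction = 0.25,
                          sero_link_strength = 0.8,
                          carrier_prob_enriched = 0.9,
                          carrier_prob_other = 0.1,
                          planted_peptides_per_motif = 4L,
                          timepoint_noise_sd = 0.2,
                          n_decoy_epitopes = 30L,
                          n_autoantigen_decoys = 8L,
                          shared_peptides = 100L,
                          sero_background_rate = 0.15,
                          rng_seed = 1L) {
  d <- as.list(environment())
  frac <- c("subject_core_fraction", "planted_reverse_fraction", "sero_link_strength",
            "carrier_prob_enriched", "carrier_prob_other", "sero_background_rate")
  for (f in frac) if (d[[f]] < 0 || d[[f]] > 1)
    abort_mimo(paste0(f, " must lie in [0, 1]"), "mimo_design_error")
  if (d$planted_effect <= 1) abort_mimo("planted_effect must exceed 1", "mimo_design_error")
  if (d$peptides_per_sample < 10L) abort_mimo("peptides_per_sample too small", "mimo_design_error")
  if (d$n_planted_motifs < 0L) abort_mimo("n_planted_motifs must be >= 0", "mimo_design_error")
  if (d$shared_peptides < 0L || d$shared_peptides >= d$peptides_per_sample)
    abort_mimo("shared_peptides must be >= 0 and below peptides_per_sample", "mimo_design_error")
  structure(d, class = "mimo_design")
}

# one random gapped pattern: span 5-11, five fixed residues, fixed flanks
random_motif_pattern <- function(span_min = 5L, span_max = 11L, n_fixed = 5L,
                                 distinct_residues = TRUE) {
  span <- sample(span_min:span_max, 1L)
  pos <- if (span == n_fixed) seq_len(span) else
    sort(c(1L, span, sample(setdiff(2:(span - 1L), integer(0)), n_fixed - 2L)))
  res <- sample(AA_ALPHABET, n_fixed, replace = !distinct_residues)
  pat <- rep(".", span)
  pat[pos] <- res
  paste(pat, collapse = "")
}

# instantiate n distinct 12-mers consistent with a wildcard pattern at a
# random offset (random residues at wildcard and flanking positions)
instantiate_motif_peptides <- function(pattern, n) {
  span <- nchar(pattern)
  chars <- strsplit(pattern, "")[[1]]
  out <- character(0)
  guard <- 0L
  while (length(out) < n && guard < 50L * n) {
    guard <- guard + 1L
    off <- sample.int(PEPTIDE_LENGTH - span + 1L, 1L)
    pep <- sample(AA_ALPHABET, PEPTIDE_LENGTH, replace = TRUE)
    fixed <- chars != "."
    pep[(off:(off + span - 1L))[fixed]] <- chars[fixed]
    out <- unique(c(out, paste(pep, collapse = "")))
  }
  out[seq_len(n)]
}

# embed a pattern instance inside a longer random sequence; returns the
# sequence (the instance occurs as an exact wildcard match by construction)
embed_motif_in_sequence <- function(pattern, total_len = NULL) {
  span <- nchar(pattern)
  if (is.null(total_len)) total_len <- span + sample(4:12, 1L)
  chars <- strsplit(pattern, "")[[1]]
  inst <- ifelse(chars == ".", sample(AA_ALPHABET, span, replace = TRUE), chars)
  lead <- sample.int(total_len - span + 1L, 1L) - 1L
  paste0(paste(sample(AA_ALPHABET, lead, replace = TRUE), collapse = ""),
         paste(inst, collapse = ""),
         paste(sample(AA_ALPHABET, total_len - span - lead, replace = TRUE), collapse = ""))
}

lognormal_counts <- function(n, meanlog, sdlog) {
  pmax(1, round(stats::rlnorm(n, meanlog, sdlog)))
}

#' Generate a complete synthetic cohort
#'
#' Produces repertoires (two timepoints per subject), metadata with
#' serostatus, a mock reference epitope database containing every planted
#' motif, and the ground truth. The ground truth is emitted alongside the
#' data and is never consumed by the pipeline.
#'
#' Generation is bit-reproducible given `design$rng_seed`. Each subject has a
#' persistent core of peptides resampled at T2 with small multiplicative
#' log-normal noise (driving high paired cosine similarity) plus independent
#' background. Carrier subjects of a planted motif receive distinct
#' motif-matching peptides whose counts are scaled by `planted_effect`.
#'
#' @param design a [cohort_design()].
#' @return list with elements `repertoires` (named list), `metadata`
#'   (data.frame), `reference` (data.frame) and `ground_truth` (list with
#'   `planted_motifs` data.frame, `carriers` logical matrix subjects x motifs,
#'   `subject_effects` matrix of realized multipliers, `shared_peptides`
#'   public pool).
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_design(n_case_subjects = 3,
#'   n_control_subjects = 3, n_qc_subjects = 1, peptides_per_sample = 50,
#'   n_planted_motifs = 1, rng_seed = 7))
#' names(cohort)
generate_cohort <- function(design) {
  stopifnot(inherits(design, "mimo_design"))
  with_seed(design$rng_seed, {
    groups <- c(rep("CPSNP", design$n_case_subjects),
                rep("nonCPSNP", design$n_control_subjects),
                rep("CTRL", design$n_qc_subjects))
    n_subj <- length(groups)
    subjects <- sprintf("SUBJ%03d", seq_len(n_subj))

    # planted motifs and directions
    n_rev <- floor(design$planted_reverse_fraction * design$n_planted_motifs)
    n_pm <- design$n_planted_motifs
    planted <- character(0)
    guard <- 0L
    while (length(planted) < n_pm) {
      guard <- guard + 1L
      if (guard > 200L * max(1L, n_pm))
        abort_mimo("cannot construct the requested number of distinct planted motifs",
                   "mimo_design_error")
      planted <- unique(c(planted, random_motif_pattern()))
    }
    planted <- planted[seq_len(n_pm)]
    direction <- rep("case", n_pm)
    if (n_rev > 0L) direction[seq_len(n_rev)] <- "control"

    # carrier assignment per subject x motif
    carriers <- matrix(FALSE, n_subj, max(1L, n_pm),
                       dimnames = list(subjects, if (n_pm) planted else "none"))
    if (n_pm > 0L) {
      for (m in seq_len(n_pm)) {
        enriched <- if (direction[m] == "case") groups == "CPSNP" else groups == "nonCPSNP"
        p <- ifelse(enriched, design$carrier_prob_enriched, design$carrier_prob_other)
        carriers[, m] <- stats::runif(n_subj) < p
      }
    }

    # planted peptides per carrier subject x motif (distinct per subject)
    planted_peps <- vector("list", n_subj)
    subject_effects <- matrix(1, n_subj, max(1L, n_pm), dimnames = dimnames(carriers))
    for (j in seq_len(n_subj)) {
      pl <- list()
      if (n_pm > 0L) for (m in seq_len(n_pm)) {
        if (carriers[j, m]) {
          peps <- instantiate_motif_peptides(planted[m], design$planted_peptides_per_motif)
          base <- lognormal_counts(length(peps), design$background_log_mean, design$background_log_sd)
          eff <- design$planted_effect * exp(stats::rnorm(1, 0, 0.1))
          subject_effects[j, m] <- eff
          pl[[length(pl) + 1L]] <- stats::setNames(base * eff, peps)
        }
      }
      planted_peps[[j]] <- if (length(pl)) unlist(pl) else numeric(0)
    }

    # repertoires: public pool + persistent private core + independent
    # background per timepoint
    n_shared <- design$shared_peptides
    n_core <- round(design$subject_core_fraction * (design$peptides_per_sample - n_shared))
    n_bg <- design$peptides_per_sample - n_shared - n_core
    shared_peps <- random_aa_strings(n_shared)
    reps <- list()
    meta_rows <- list()
    for (j in seq_len(n_subj)) {
      core_peps <- random_aa_strings(n_core)
      core_cts <- lognormal_counts(n_core, design$background_log_mean, design$background_log_sd)
      shared_cts <- lognormal_counts(n_shared, design$background_log_mean, design$background_log_sd)
      for (tp in c("T1", "T2")) {
        bg_peps <- random_aa_strings(n_bg)
        bg_cts <- lognormal_counts(n_bg, design$background_log_mean, design$background_log_sd)
        if (tp == "T1") {
          cc <- core_cts
          sc <- shared_cts
          pp <- planted_peps[[j]]
        } else {
          noise <- exp(stats::rnorm(n_core, 0, design$timepoint_noise_sd))
          cc <- pmax(1, round(core_cts * noise))
          sc <- pmax(1, round(shared_cts * exp(stats::rnorm(n_shared, 0, design$timepoint_noise_sd))))
          pp <- planted_peps[[j]]
          if (length(pp))  # pmax(1, .) drops names; restore them
            pp <- stats::setNames(
              pmax(1, round(pp * exp(stats::rnorm(length(pp), 0, design$timepoint_noise_sd)))),
              names(pp))
        }
        counts <- c(stats::setNames(cc, core_peps), stats::setNames(bg_cts, bg_peps),
                    stats::setNames(sc, shared_peps))
        if (length(pp)) counts <- c(counts, round(pp))
        sid <- paste0(subjects[j], "_", tp)
        reps[[sid]] <- repertoire(sid, counts)
        meta_rows[[length(meta_rows) + 1L]] <- data.table::data.table(
          sample_id = sid, subject_id = subjects[j], timepoint = tp,
          group = groups[j],
          age = round(stats::rnorm(1, if (tp == "T1") 55 else 61, 7), 1),
          bmi = round(stats::rnorm(1, 26, 4), 1))
      }
    }
    metadata <- as.data.frame(data.table::rbindlist(meta_rows))

    # serostatus: one mock virus per planted motif; POS links to carriage
    if (n_pm > 0L) {
      for (m in seq_len(n_pm)) {
        virus <- sprintf("MockVirus%02d", m)
        p <- ifelse(carriers[metadata$subject_id, m],
                    design$sero_link_strength, design$sero_background_rate)
        status <- ifelse(stats::runif(nrow(metadata)) < p, "POS", "NEG")
        status[stats::runif(nrow(metadata)) < 0.05] <- "B"
        # serostatus is a subject-level property measured at T1
        t1 <- metadata$timepoint == "T1"
        subj_status <- stats::setNames(status[t1], metadata$subject_id[t1])
        metadata[[paste0("sero_", virus)]] <- subj_status[metadata$subject_id]
      }
    }

    # reference database: planted epitopes + decoys + autoantigen mimic
    ref_rows <- list()
    if (n_pm > 0L) for (m in seq_len(n_pm)) {
      ref_rows[[length(ref_rows) + 1L]] <- data.table::data.table(
        epitope_id = sprintf("EPI_PLANT_%02d", m),
        sequence = embed_motif_in_sequence(planted[m]),
        antigen = sprintf("MockAntigen%02d", m),
        organism = sprintf("MockVirus%02d", m),
        category = "pathogen", cellular_location = NA_character_)
    }
    # the first planted motif is also embedded in a mock human antigen so the
    # autoantigen mimicry cross-mapping has a positive instance
    if (n_pm > 0L) {
      ref_rows[[length(ref_rows) + 1L]] <- data.table::data.table(
        epitope_id = "EPI_AUTO_MIMIC",
        sequence = embed_motif_in_sequence(planted[1L]),
        antigen = "MockHumanProtein01", organism = "Homo sapiens",
        category = "autoantigen", cellular_location = "Cell membrane")
    }
    if (design$n_decoy_epitopes > 0L) {
      ref_rows[[length(ref_rows) + 1L]] <- data.table::data.table(
        epitope_id = sprintf("EPI_DECOY_%02d", seq_len(design$n_decoy_epitopes)),
        sequence = random_aa_strings(design$n_decoy_epitopes, sample(9:25, design$n_decoy_epitopes, replace = TRUE)),
        antigen = sprintf("DecoyAntigen%02d", seq_len(design$n_decoy_epitopes)),
        organism = sprintf("DecoyOrganism%02d", seq_len(design$n_decoy_epitopes)),
        category = "pathogen", cellular_location = NA_character_)
    }
    if (design$n_autoantigen_decoys > 0L) {
      locs <- c("Nucleus", "Cytoplasm", "Secreted", "Cell membrane", "Mitochondrion")
      ref_rows[[length(ref_rows) + 1L]] <- data.table::data.table(
        epitope_id = sprintf("EPI_AUTODECOY_%02d", seq_len(design$n_autoantigen_decoys)),
        sequence = random_aa_strings(design$n_autoantigen_decoys, sample(9:25, design$n_autoantigen_decoys, replace = TRUE)),
        antigen = sprintf("DecoyHumanProtein%02d", seq_len(design$n_autoantigen_decoys)),
        organism = "Homo sapiens",
        category = "autoantigen",
        cellular_location = sample(locs, design$n_autoantigen_decoys, replace = TRUE))
    }
    reference <- as.data.frame(data.table::rbindlist(ref_rows))

    ground_truth <- list(
      planted_motifs = if (n_pm > 0L)
        data.frame(pattern = planted, direction = direction,
                   epitope_id = sprintf("EPI_PLANT_%02d", seq_len(n_pm)),
                   organism = sprintf("MockVirus%02d", seq_len(n_pm)),
                   stringsAsFactors = FALSE)
      else data.frame(pattern = character(0), direction = character(0),
                      epitope_id = character(0), organism = character(0)),
      carriers = carriers,
      subject_effects = subject_effects,
      shared_peptides = shared_peps)

    list(repertoires = reps, metadata = metadata, reference = reference,
         ground_truth = ground_truth)
  })
}

#' Tabulate serostatus by group
#'
#' Builds, for each virus column in the metadata, the group x {POS, NEG, B}
#' count table (one row per group; subjects counted once via their T1 sample).
#' Row marginals equal group sizes.
#'
#' @param metadata metadata data.frame with `sero_<virus>` columns.
#' @return data.frame with columns `virus`, `group`, `POS`, `NEG`, `B`.
#' @export
generate_serology_table <- function(metadata) {
  sero_cols <- grep("^sero_", names(metadata), value = TRUE)
  if (!length(sero_cols)) abort_mimo("metadata has no serostatus columns", "mimo_validation_error")
  t1 <- metadata[metadata$timepoint == "T1", , drop = FALSE]
  grps <- unique(metadata$group)
  out <- list()
  for (sc in sero_cols) {
    virus <- sub("^sero_", "", sc)
    for (g in grps) {
      v <- t1[[sc]][t1$group == g]
      out[[length(out) + 1L]] <- data.frame(
        virus = virus, group = g,
        POS = sum(v == "POS", na.rm = TRUE),
        NEG = sum(v == "NEG", na.rm = TRUE),
        B = sum(v == "B", na.rm = TRUE),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Write ground truth to TSV
#'
#' @param ground_truth the `ground_truth` element of [generate_cohort()].
#' @param path output TSV path.
#' @export
write_ground_truth <- function(ground_truth, path) {
  data.table::fwrite(ground_truth$planted_motifs, path, sep = "\t")
  invisible(path)
}
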