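# Small in-code fixtures shared across test files.

# a tiny deterministic repertoire from explicit peptides/counts
fix_repertoire <- function(id, peptides, counts) {
  repertoire(id, stats::setNames(counts, peptides))
}

# distinct valid 12-mers: AAAAAAAAAAAA with a varying tail index
fix_peptides <- function(n, prefix = "AAAAAAAAA") {
  stopifnot(n <= 400)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  grid <- expand.grid(a = aa, b = aa, stringsAsFactors = FALSE)
  paste0(prefix, "A", grid$a, grid$b)[seq_len(n)]
}

# fast small cohort for pipeline-level tests; ... overrides any default
fix_small_design <- function(seed = 1L, n_planted = 2L, ...) {
  defaults <- list(n_case_subjects = 6L, n_control_subjects = 6L, n_qc_subjects = 2L,
                   peptides_per_sample = 150L, shared_peptides = 30L,
                   n_planted_motifs = n_planted, planted_effect = 8,
                   planted_reverse_fraction = 0, rng_seed = seed)
  do.call(cohort_design, utils::modifyList(defaults, list(...)))
}

fix_small_config <- function(...) {
  defaults <- list(top_k = 100L, discover_top = 100L, max_candidates = 60L,
                   min_samples = 3L, n_permutations = 400L,
                   tsne_perplexity = 5, cv_folds = 3L)
  do.call(pipeline_config, utils::modifyList(defaults, list(...)))
}

# metadata frame for n subjects x two timepoints
fix_two_timepoint_metadata <- function(n_subjects, group = "CPSNP") {
  subj <- sprintf("S%03d", seq_len(n_subjects))
  data.frame(sample_id = c(paste0(subj, "_T1"), paste0(subj, "_T2")),
             subject_id = rep(subj, 2L),
             timepoint = rep(c("T1", "T2"), each = n_subjects),
             group = group, stringsAsFactors = FALSE)
}
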