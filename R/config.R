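#' Pipeline configuration
#'
#' Creates the configuration object holding every fixed constant of the
#' analysis. Defaults are the published parameters of the profiling method:
#' top-5000 peptide immunoprofiles, a 0.70 paired-CSI QC floor, counts
#' normalized to 3 million reads, selection thresholds p < 0.05 and
#' Youden J > 0.25, 10,000 permutations, t-SNE (dims 2, perplexity 15,
#' max_iter 500), DBSCAN (epsilon 2, minPts 10), 5-fold cross-validation,
#' and gapped motifs spanning 5-11 positions with exactly five fixed residues.
#'
#' @param top_k number of most abundant peptides per sample entering the
#'   similarity analysis.
#' @param csi_pair_min paired cosine-similarity floor below which both samples
#'   of a subject are excluded from group analyses.
#' @param normalization_total read total that every repertoire is scaled to
#'   before seroreactivity summarization.
#' @param select_p_max,select_youden_min t-test p-value ceiling and Youden-J
#'   floor for feature selection.
#' @param n_permutations permutations for the motif-alignment null and the
#'   classifier label-permutation test.
#' @param tsne_dims,tsne_perplexity,tsne_max_iter t-SNE embedding parameters.
#' @param dbscan_epsilon,dbscan_min_pts DBSCAN clustering parameters applied
#'   to the embedded coordinates.
#' @param cv_folds number of stratified cross-validation folds.
#' @param motif_span_min,motif_span_max,motif_fixed motif geometry: span
#'   bounds and the exact number of fixed (non-wildcard) positions.
#' @param rng_seed master seed; all stage seeds derive from it.
#' @param welch if `TRUE` use Welch's unequal-variance t-test instead of the
#'   classical pooled-variance Student test.
#' @param min_count minimum read count for a peptide to establish motif
#'   presence in a sample during discovery.
#' @param max_candidates maximum number of ranked motifs returned by
#'   discovery.
#' @param discover_top number of most abundant peptides per sample that seed
#'   pattern instantiation during discovery.
#' @param min_samples minimum number of samples a candidate pattern must be
#'   present in to be scored.
#' @param ridge L2 penalty applied to the logistic fit when complete
#'   separation is detected.
#' @param log_base,pseudocount log transform used for seroreactivity values:
#'   `log(pseudocount + x, base = log_base)`.
#' @return a named list of class `mimo_config`.
#' @export
#' @examples
#' cfg <- pipeline_config(top_k = 100, n_permutations = 200)
#' cfg$csi_pair_min
pipeline_config <- function(top_k = 5000L,
                            csi_pair_min = 0.70,
                            normalization_total = 3e6,
                            select_p_max = 0.05,
                            select_youden_min = 0.25,
                            n_permutations = 10000L,
                            tsne_dims = 2L,
                            tsne_perplexity = 15,
                            tsne_max_iter = 500L,
                            dbscan_epsilon = 2,
                            dbscan_min_pts = 10L,
                            cv_folds = 5L,
                            motif_span_min = 5L,
                            motif_span_max = 11L,
                            motif_fixed = 5L,
                            rng_seed = 1L,
                            welch = FALSE,
                            min_count = 1L,
                            max_candidates = 1000L,
                            discover_top = 500L,
                            min_samples = 3L,
                            ridge = 1e-6,
                            log_base = 10,
                            pseudocount = 1) {
  cfg <- list(
    top_k = as.integer(top_k), csi_pair_min = csi_pair_min,
    normalization_total = normalization_total,
    select_p_max = select_p_max, select_youden_min = select_youden_min,
    n_permutations = as.integer(n_permutations),
    tsne_dims = as.integer(tsne_dims), tsne_perplexity = tsne_perplexity,
    tsne_max_iter = as.integer(tsne_max_iter),
    dbscan_epsilon = dbscan_epsilon, dbscan_min_pts = as.integer(dbscan_min_pts),
    cv_folds = as.integer(cv_folds),
    motif_span_min = as.integer(motif_span_min),
    motif_span_max = as.integer(motif_span_max),
    motif_fixed = as.integer(motif_fixed),
    rng_seed = as.integer(rng_seed), welch = isTRUE(welch),
    min_count = as.integer(min_count),
    max_candidates = as.integer(max_candidates),
    discover_top = as.integer(discover_top),
    min_samples = as.integer(min_samples),
    ridge = ridge, log_base = log_base, pseudocount = pseudocount
  )
  class(cfg) <- "mimo_config"
  validate_config(cfg)
  cfg
}

#' Validate a pipeline configuration
#'
#' Checks every field against its stated domain; called by [pipeline_config()]
#' and again by [run_pipeline()] before any stage executes.
#'
#' @param cfg a `mimo_config` list.
#' @return the config, invisibly, if valid; otherwise an error.
#' @export
validate_config <- function(cfg) {
  chk <- function(ok, what) if (!ok) abort_mimo(paste0("invalid config: ", what), "mimo_config_error")
  chk(cfg$top_k >= 1L, "top_k must be >= 1")
  chk(cfg$csi_pair_min > 0 && cfg$csi_pair_min < 1, "csi_pair_min must lie in (0, 1)")
  chk(cfg$normalization_total > 0, "normalization_total must be positive")
  chk(cfg$select_p_max > 0 && cfg$select_p_max <= 1, "select_p_max must lie in (0, 1]")
  chk(cfg$select_youden_min >= 0 && cfg$select_youden_min < 1, "select_youden_min must lie in [0, 1)")
  chk(cfg$n_permutations >= 1L, "n_permutations must be >= 1")
  chk(cfg$tsne_perplexity > 0, "tsne_perplexity must be positive")
  chk(cfg$dbscan_epsilon > 0, "dbscan_epsilon must be positive")
  chk(cfg$dbscan_min_pts >= 1L, "dbscan_min_pts must be >= 1")
  chk(cfg$cv_folds >= 2L, "cv_folds must be >= 2")
  chk(cfg$motif_span_min >= cfg$motif_fixed, "motif_fixed must not exceed motif_span_min")
  chk(cfg$motif_span_max >= cfg$motif_span_min, "motif_span_max must be >= motif_span_min")
  chk(cfg$motif_span_max <= PEPTIDE_LENGTH, "motif_span_max must not exceed the peptide length")
  chk(cfg$min_count >= 1L, "min_count must be >= 1")
  chk(cfg$pseudocount > 0, "pseudocount must be positive")
  invisible(cfg)
}

#' Read / write configuration files
#'
#' Configurations are stored as flat YAML with keys mirroring
#' [pipeline_config()] argument names bit-exactly; unknown keys error.
#'
#' @param path YAML file path.
#' @return `read_config` returns a validated `mimo_config`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) abort_mimo(paste0("config file not found: ", path), "mimo_io_error")
  vals <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) abort_mimo(paste0("unknown config keys: ", paste(bad, collapse = ", ")), "mimo_config_error")
  do.call(pipeline_config, vals)
}

#' @rdname read_config
#' @param cfg a `mimo_config`.
#' @export
write_config <- function(cfg, path) {
  validate_config(cfg)
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}
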