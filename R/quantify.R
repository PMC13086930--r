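#' Normalize a repertoire to a fixed read total
#'
#' Each count is multiplied by `normalization_total / total_reads`, so scaled
#' counts sum to the normalization total exactly (up to float epsilon).
#'
#' @param rep a [repertoire()].
#' @param normalization_total target read total (default 3 million).
#' @return a repertoire-shaped list with scaled (non-integer) counts.
#' @export
normalize_repertoire <- function(rep, normalization_total = 3e6) {
  if (rep$total_reads <= 0) abort_mimo("zero total reads", "mimo_validation_error")
  f <- normalization_total / rep$total_reads
  structure(list(sample_id = rep$sample_id, counts = rep$counts * f,
                 total_reads = normalization_total),
            class = "mimo_repertoire")
}

#' Per-sample seroreactivity to one motif
#'
#' Summarizes a normalized repertoire against a motif:
#' `log(pseudocount + sum of normalized counts of distinct matching
#' peptides, base = log_base)`. Each distinct peptide is counted once with
#' its normalized count; no matching peptides yield `log(pseudocount)` (0 at
#' the defaults).
#'
#' @param rep_norm a normalized repertoire ([normalize_repertoire()]).
#' @param pattern motif string.
#' @param log_base,pseudocount transform parameters (defaults log10, 1).
#' @return scalar log seroreactivity.
#' @export
epitope_abundance <- function(rep_norm, pattern, log_base = 10, pseudocount = 1) {
  hit <- motif_matches(pattern, names(rep_norm$counts))
  log(pseudocount + sum(rep_norm$counts[hit]), base = log_base)
}

#' Wilcoxon rank-sum test
#'
#' Midranks for ties; exact p for combined n <= 20 without ties, normal
#' approximation with tie and continuity correction otherwise.
#'
#' @param g1,g2 numeric vectors.
#' @return list with `W` (rank-sum statistic of `g1`) and `p` (two-sided).
#' @export
wilcoxon_rank_sum <- function(g1, g2) {
  if (!length(g1) || !length(g2)) abort_mimo("both groups must be non-empty", "mimo_validation_error")
  ties <- anyDuplicated(c(g1, g2)) > 0L
  ht <- suppressWarnings(stats::wilcox.test(
    g1, g2, exact = !ties && (length(g1) + length(g2) <= 20L), correct = TRUE))
  list(W = unname(ht$statistic), p = ht$p.value)
}

#' Spearman rank correlation
#'
#' Pearson correlation of midranks; exact permutation p for n <= 8 without
#' ties, asymptotic t approximation otherwise. A constant vector has no
#' defined rank correlation and returns NA.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return list with `rho` and `p` (two-sided; NA when rho is undefined).
#' @export
spearman_correlation <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L)
    abort_mimo("need equal lengths >= 3", "mimo_validation_error")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(list(rho = NA_real_, p = NA_real_))
  n <- length(x)
  ties <- anyDuplicated(x) > 0L || anyDuplicated(y) > 0L
  ht <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                         exact = !ties && n <= 8L))
  list(rho = unname(ht$estimate), p = ht$p.value)
}

#' Embed epitopes and cluster the embedding
#'
#' Embeds the rows of a log-abundance feature matrix (epitopes x samples)
#' into 2-D with t-SNE at the configured perplexity and iteration count,
#' then clusters the coordinates with DBSCAN at the configured epsilon and
#' minPts. Labels are deterministic given the seed; label 0 marks noise.
#' Contract-level guarantees only: the labels partition the epitopes and
#' noise is allowed.
#'
#' @param feature_matrix epitopes x samples numeric matrix.
#' @param config a [pipeline_config()] (t-SNE and DBSCAN parameters).
#' @param seed embedding seed.
#' @return list with `coords` (n x 2 matrix) and `cluster` (integer labels,
#'   0 = noise), both row-aligned with `feature_matrix`.
#' @export
embed_and_cluster <- function(feature_matrix, config = pipeline_config(),
                              seed = config$rng_seed) {
  n <- nrow(feature_matrix)
  if (n < 3 * config$tsne_perplexity)
    abort_mimo(sprintf(
      "too few epitopes (%d) for perplexity %.0f; need >= %d or lower the perplexity to <= %.0f",
      n, config$tsne_perplexity, ceiling(3 * config$tsne_perplexity), floor(n / 3)),
      "mimo_validation_error")
  coords <- tsne_embed(feature_matrix, dims = config$tsne_dims,
                       perplexity = config$tsne_perplexity,
                       max_iter = config$tsne_max_iter, seed = seed)
  cl <- dbscan_cluster(coords, eps = config$dbscan_epsilon,
                       min_pts = config$dbscan_min_pts)
  list(coords = coords, cluster = cl)
}

#' Summarized seroreactivity with group comparisons
#'
#' Sums the feature matrix over the epitope set per sample, runs Wilcoxon
#' rank-sum tests between all group pairs with Benjamini-Hochberg
#' adjustment, and computes the per-group T1-vs-T2 Spearman correlation of
#' the summarized values over subjects with both timepoints. Groups with
#' fewer than two samples are skipped with a warning.
#'
#' @param feature_matrix epitopes x samples log-abundance matrix.
#' @param metadata metadata data.frame covering the matrix columns.
#' @return list with `per_sample` (data.frame sample/subject/timepoint/group/
#'   summarized value), `group_tests` (pairwise Wilcoxon with `p` and
#'   `fdr_q`), and `paired_spearman` (per-group rho and p across timepoints).
#' @export
group_response_summary <- function(feature_matrix, metadata) {
  md <- metadata[match(colnames(feature_matrix), metadata$sample_id), , drop = FALSE]
  if (anyNA(md$sample_id)) abort_mimo("metadata does not cover all samples", "mimo_validation_error")
  per_sample <- data.frame(sample_id = md$sample_id, subject_id = md$subject_id,
                           timepoint = md$timepoint, group = md$group,
                           summarized = colSums(feature_matrix),
                           stringsAsFactors = FALSE)
  grps <- unique(per_sample$group)
  combos <- if (length(grps) >= 2L) utils::combn(grps, 2L, simplify = FALSE) else list()
  tests <- list()
  for (cb in combos) {
    v1 <- per_sample$summarized[per_sample$group == cb[1]]
    v2 <- per_sample$summarized[per_sample$group == cb[2]]
    if (length(v1) < 2L || length(v2) < 2L) {
      warning("group with < 2 samples: skipping ", cb[1], " vs ", cb[2])
      next
    }
    wt <- wilcoxon_rank_sum(v1, v2)
    tests[[length(tests) + 1L]] <- data.frame(
      group1 = cb[1], group2 = cb[2], W = wt$W, p = wt$p, stringsAsFactors = FALSE)
  }
  group_tests <- if (length(tests)) do.call(rbind, tests) else
    data.frame(group1 = character(0), group2 = character(0), W = numeric(0), p = numeric(0))
  if (nrow(group_tests)) group_tests$fdr_q <- fdr_adjust(group_tests$p)
  sp <- list()
  for (g in grps) {
    sub <- per_sample[per_sample$group == g, , drop = FALSE]
    t1 <- sub[sub$timepoint == "T1", ]; t2 <- sub[sub$timepoint == "T2", ]
    shared <- intersect(t1$subject_id, t2$subject_id)
    if (length(shared) < 3L) next
    x <- t1$summarized[match(shared, t1$subject_id)]
    y <- t2$summarized[match(shared, t2$subject_id)]
    sc <- spearman_correlation(x, y)
    sp[[length(sp) + 1L]] <- data.frame(group = g, n_subjects = length(shared),
                                        rho = sc$rho, p = sc$p, stringsAsFactors = FALSE)
  }
  paired_spearman <- if (length(sp)) do.call(rbind, sp) else
    data.frame(group = character(0), n_subjects = integer(0), rho = numeric(0), p = numeric(0))
  list(per_sample = per_sample, group_tests = group_tests,
       paired_spearman = paired_spearman)
}
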