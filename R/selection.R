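#' Two-sample t-test on log abundances
#'
#' Classical pooled-variance Student test by default (`welch = FALSE`), with
#' Welch's unequal-variance form as an option. Degenerate inputs follow the
#' conventions: zero pooled variance with equal means gives t = 0, p = 1;
#' zero variance with unequal means is an error (the contrast is not a
#' t-statistic there).
#'
#' @param g1,g2 numeric vectors (>= 2 values each).
#' @param welch use Welch's test instead of the pooled-variance Student form.
#' @return list with `t`, `p` (two-sided) and `df`.
#' @export
student_t_test <- function(g1, g2, welch = FALSE) {
  if (length(g1) < 2L || length(g2) < 2L)
    abort_mimo("need >= 2 values per group", "mimo_validation_error")
  pooled_var <- (sum((g1 - mean(g1))^2) + sum((g2 - mean(g2))^2)) /
    (length(g1) + length(g2) - 2L)
  if (pooled_var == 0) {
    if (isTRUE(all.equal(mean(g1), mean(g2)))) return(list(t = 0, p = 1, df = length(g1) + length(g2) - 2L))
    abort_mimo("zero variance with unequal means: degenerate input", "mimo_validation_error")
  }
  ht <- stats::t.test(g1, g2, var.equal = !welch)
  list(t = unname(ht$statistic), p = ht$p.value, df = unname(ht$parameter))
}

#' Youden-optimal cutpoint between two groups
#'
#' Scans candidate cutpoints at midpoints between adjacent sorted unique
#' pooled values and returns the cutpoint maximizing
#' J = sensitivity + specificity - 1, with the positive group (`g1`) called
#' positive above the cutpoint. The orientation (above vs below) is chosen so
#' that J >= 0; ties in J are broken by the smallest cutpoint. J is invariant
#' under strictly monotone transforms of the values.
#'
#' @param g1 values of the positive group (cases).
#' @param g2 values of the negative group.
#' @return list with `cutpoint`, `youden_j`, `direction` (`">"` means
#'   positive above the cutpoint), `sensitivity`, `specificity`.
#' @export
youden_optimal_cutpoint <- function(g1, g2) {
  if (!length(g1) || !length(g2)) abort_mimo("both groups must be non-empty", "mimo_validation_error")
  u <- sort(unique(c(g1, g2)))
  if (length(u) == 1L)
    return(list(cutpoint = u, youden_j = 0, direction = ">",
                sensitivity = 0, specificity = 1))
  cuts <- (u[-1] + u[-length(u)]) / 2
  best <- list(j = -Inf, cut = NA_real_, dir = ">", sens = NA_real_, spec = NA_real_)
  for (ct in cuts) {
    sens_gt <- mean(g1 > ct); spec_gt <- mean(g2 <= ct)
    j_gt <- sens_gt + spec_gt - 1
    sens_lt <- mean(g1 < ct); spec_lt <- mean(g2 >= ct)
    j_lt <- sens_lt + spec_lt - 1
    if (j_gt >= j_lt) {
      if (j_gt > best$j + 1e-12)
        best <- list(j = j_gt, cut = ct, dir = ">", sens = sens_gt, spec = spec_gt)
    } else {
      if (j_lt > best$j + 1e-12)
        best <- list(j = j_lt, cut = ct, dir = "<", sens = sens_lt, spec = spec_lt)
    }
  }
  list(cutpoint = best$cut, youden_j = max(0, best$j), direction = best$dir,
       sensitivity = best$sens, specificity = best$spec)
}

#' Build a motif log-abundance feature matrix
#'
#' For every motif and sample: normalize the repertoire to the configured
#' read total, sum the normalized counts of all distinct peptides matching
#' the motif, and log-transform with a pseudocount
#' (`log(pseudocount + sum, base = log_base)`).
#'
#' @param repertoires named list of repertoires.
#' @param patterns character vector of motif patterns.
#' @param config a [pipeline_config()].
#' @return numeric matrix, motifs (rows) x samples (columns).
#' @export
epitope_feature_matrix <- function(repertoires, patterns, config = pipeline_config()) {
  ids <- vapply(repertoires, `[[`, character(1), "sample_id")
  norm <- lapply(repertoires, normalize_repertoire,
                 normalization_total = config$normalization_total)
  # match each pattern once against the union of peptides
  upep <- sort(unique(unlist(lapply(norm, function(r) names(r$counts)), use.names = FALSE)))
  M <- matrix(0, nrow = length(patterns), ncol = length(norm),
              dimnames = list(patterns, ids))
  for (i in seq_along(patterns)) {
    hit <- upep[motif_matches(patterns[i], upep)]
    if (!length(hit)) next
    M[i, ] <- vapply(norm, function(r) {
      idx <- intersect(hit, names(r$counts))
      sum(r$counts[idx])
    }, numeric(1))
  }
  log(config$pseudocount + M, base = config$log_base)
}

#' Select group-differentiating motif features
#'
#' For each motif the per-timepoint group contrast is evaluated with the
#' log-abundance t-test and the Youden-optimal cutpoint; a motif is selected
#' at a timepoint when p < `select_p_max` and J > `select_youden_min`, and
#' the overall selected set is the union over timepoints (per-timepoint
#' flags retained). Constant features yield p = 1, J = 0, not selected.
#'
#' @param feature_matrix motifs x samples log-abundance matrix
#'   ([epitope_feature_matrix()]).
#' @param metadata metadata data.frame covering the matrix columns.
#' @param case_group group label treated as positive (default `"CPSNP"`).
#' @param config a [pipeline_config()].
#' @param control_groups group labels forming the comparison set; defaults to
#'   all non-case groups present.
#' @return `data.frame` with one row per motif x timepoint plus the combined
#'   `selected` flag columns `selected_T1`, `selected_T2`, `selected`.
#' @export
select_features <- function(feature_matrix, metadata, case_group = "CPSNP",
                            config = pipeline_config(), control_groups = NULL) {
  md <- metadata[match(colnames(feature_matrix), metadata$sample_id), , drop = FALSE]
  if (anyNA(md$sample_id)) abort_mimo("metadata does not cover all samples", "mimo_validation_error")
  if (is.null(control_groups)) control_groups <- setdiff(unique(md$group), case_group)
  rows <- list()
  for (tp in c("T1", "T2")) {
    sel_tp <- md$timepoint == tp
    g1_idx <- sel_tp & md$group == case_group
    g2_idx <- sel_tp & md$group %in% control_groups
    if (sum(g1_idx) < 2L || sum(g2_idx) < 2L) next
    for (i in seq_len(nrow(feature_matrix))) {
      v1 <- feature_matrix[i, g1_idx]; v2 <- feature_matrix[i, g2_idx]
      if (stats::var(c(v1, v2)) == 0) {
        tt <- list(t = 0, p = 1); yj <- list(cutpoint = v1[1], youden_j = 0)
      } else {
        tt <- tryCatch(student_t_test(v1, v2, welch = config$welch),
                       mimoprofile_error = function(e) list(t = NA_real_, p = 1))
        yj <- youden_optimal_cutpoint(v1, v2)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        pattern = rownames(feature_matrix)[i], timepoint = tp,
        t_statistic = tt$t, p_value = tt$p,
        youden_j = yj$youden_j, cutpoint = yj$cutpoint,
        selected = tt$p < config$select_p_max & yj$youden_j > config$select_youden_min,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) abort_mimo("no timepoint had >= 2 samples per group", "mimo_validation_error")
  long <- do.call(rbind, rows)
  sel_t1 <- with(long[long$timepoint == "T1", ], stats::setNames(selected, pattern))
  sel_t2 <- with(long[long$timepoint == "T2", ], stats::setNames(selected, pattern))
  pats <- rownames(feature_matrix)
  long$selected_T1 <- unname(sel_t1[long$pattern] %in% TRUE)
  long$selected_T2 <- unname(sel_t2[long$pattern] %in% TRUE)
  long$selected <- long$selected_T1 | long$selected_T2
  long
}

#' Selected motif patterns from a selection table
#'
#' @param selection output of [select_features()].
#' @return character vector of unique selected patterns.
#' @export
selected_patterns <- function(selection) {
  unique(selection$pattern[selection$selected])
}
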