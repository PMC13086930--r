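#' Top-k immunoprofile of a repertoire
#'
#' Returns the k most abundant peptides with their raw read counts. Ties at
#' rank k are broken by lexicographic peptide order so the profile is
#' deterministic. If fewer than k peptides exist, all are returned.
#'
#' @param rep a [repertoire()].
#' @param k number of peptides to keep.
#' @return named numeric vector (peptide -> count).
#' @export
top_k_profile <- function(rep, k) {
  if (k < 1L) abort_mimo("k must be >= 1", "mimo_validation_error")
  cts <- rep$counts
  if (length(cts) == 0L) abort_mimo("empty repertoire", "mimo_validation_error")
  ord <- order(-cts, names(cts))
  cts[ord][seq_len(min(k, length(cts)))]
}

#' Cosine similarity of two abundance vectors
#'
#' The normalized scalar product over the union of peptide keys; absent
#' peptides contribute zero. Exactly 0 for disjoint supports and exactly 1
#' for proportional vectors; scale-invariant.
#'
#' @param a,b named non-negative numeric vectors.
#' @return similarity in `[0, 1]`.
#' @export
#' @examples
#' cosine_similarity(c(p1 = 1, p2 = 2, p3 = 2), c(p1 = 2, p2 = 1, p3 = 2)) # 8/9
cosine_similarity <- function(a, b) {
  if (!length(a) || !length(b)) abort_mimo("empty abundance vector", "mimo_validation_error")
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) abort_mimo("zero-norm abundance vector", "mimo_validation_error")
  shared <- intersect(names(a), names(b))
  if (!length(shared)) return(0)
  min(1, sum(a[shared] * b[shared]) / (na * nb))
}

#' Pairwise cosine-similarity matrix of top-k immunoprofiles
#'
#' Computes all pairwise cosine similarities of the top-k profiles (raw read
#' counts; cosine is scale-invariant) across samples. Internally the profiles
#' are laid out as a sparse sample x peptide matrix and the similarities are
#' obtained by a normalized cross-product.
#'
#' @param repertoires named list of repertoires.
#' @param k profile size (peptides per sample).
#' @return symmetric numeric matrix with unit diagonal, sample ids as
#'   dimnames; class `mimo_similarity`.
#' @export
similarity_matrix <- function(repertoires, k) {
  if (length(repertoires) < 2L) abort_mimo("need at least two repertoires", "mimo_validation_error")
  profs <- lapply(repertoires, top_k_profile, k = k)
  ids <- unname(vapply(repertoires, `[[`, character(1), "sample_id"))
  peps <- sort(unique(unlist(lapply(profs, names), use.names = FALSE)))
  i <- rep(seq_along(profs), lengths(profs))
  j <- match(unlist(lapply(profs, names), use.names = FALSE), peps)
  x <- unlist(profs, use.names = FALSE)
  M <- Matrix::sparseMatrix(i = i, j = j, x = x,
                            dims = c(length(profs), length(peps)))
  nrm <- sqrt(Matrix::rowSums(M^2))
  S <- as.matrix(Matrix::tcrossprod(M / nrm))
  S[S > 1] <- 1; S[S < 0] <- 0
  diag(S) <- 1
  S <- (S + t(S)) / 2
  dimnames(S) <- list(ids, ids)
  class(S) <- c("mimo_similarity", class(S))
  S
}

# same-subject T1/T2 sample pairs present in the matrix
paired_sample_table <- function(mat, metadata) {
  ids <- rownames(mat)
  md <- metadata[metadata$sample_id %in% ids, , drop = FALSE]
  wide <- split(md, md$subject_id)
  rows <- lapply(wide, function(s) {
    t1 <- s$sample_id[s$timepoint == "T1"]
    t2 <- s$sample_id[s$timepoint == "T2"]
    if (length(t1) == 1L && length(t2) == 1L)
      data.frame(subject_id = s$subject_id[1], t1 = t1, t2 = t2,
                 csi = mat[t1, t2], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) out <- data.frame(subject_id = character(0), t1 = character(0),
                                      t2 = character(0), csi = numeric(0))
  rownames(out) <- NULL
  out
}

#' Paired versus unpaired similarity summary
#'
#' Paired pairs are same-subject T1/T2 pairs; unpaired pairs are all other
#' unordered sample pairs. Subjects with a single sample contribute to the
#' unpaired set only (a message notes them). When every subject has exactly
#' two samples, `n_paired + n_unpaired == choose(n_samples, 2)`.
#'
#' @param mat a [similarity_matrix()].
#' @param metadata metadata data.frame linking samples to subjects.
#' @return list with `mean_paired`, `mean_unpaired`, `n_paired`, `n_unpaired`,
#'   and the per-subject `pairs` table.
#' @export
paired_unpaired_summary <- function(mat, metadata) {
  ids <- rownames(mat)
  pairs <- paired_sample_table(mat, metadata)
  singles <- setdiff(ids, c(pairs$t1, pairs$t2))
  md_single <- metadata$subject_id[match(singles, metadata$sample_id)]
  if (length(singles))
    message("subjects with a single sample contribute to unpaired pairs only: ",
            paste(unique(md_single), collapse = ", "))
  n <- length(ids)
  n_all <- n * (n - 1L) / 2L
  n_paired <- nrow(pairs)
  n_unpaired <- n_all - n_paired
  upper <- mat[upper.tri(mat)]
  sum_all <- sum(upper)
  sum_paired <- sum(pairs$csi)
  list(mean_paired = if (n_paired) sum_paired / n_paired else NA_real_,
       mean_unpaired = if (n_unpaired) (sum_all - sum_paired) / n_unpaired else NA_real_,
       n_paired = n_paired, n_unpaired = n_unpaired, pairs = pairs)
}

#' QC exclusion by paired similarity
#'
#' Flags both timepoint samples of any subject whose paired cosine similarity
#' falls below the threshold. Flagged samples are dropped from all downstream
#' group analyses.
#'
#' @param mat a [similarity_matrix()].
#' @param metadata metadata data.frame.
#' @param csi_pair_min exclusion threshold in (0, 1).
#' @return data.frame with columns `sample_id`, `subject_id`, `reason`
#'   (zero rows when nothing is excluded).
#' @export
qc_exclude <- function(mat, metadata, csi_pair_min = 0.70) {
  if (csi_pair_min <= 0 || csi_pair_min >= 1)
    abort_mimo("csi_pair_min must lie in (0, 1)", "mimo_validation_error")
  pairs <- paired_sample_table(mat, metadata)
  bad <- pairs[pairs$csi < csi_pair_min, , drop = FALSE]
  if (!nrow(bad))
    return(data.frame(sample_id = character(0), subject_id = character(0),
                      reason = character(0), stringsAsFactors = FALSE))
  data.frame(sample_id = c(bad$t1, bad$t2),
             subject_id = rep(bad$subject_id, 2L),
             reason = sprintf("paired CSI %.3f below %.2f", rep(bad$csi, 2L), csi_pair_min),
             stringsAsFactors = FALSE)
}

#' Write a similarity matrix as TSV
#'
#' @param mat a [similarity_matrix()].
#' @param path output path; sample ids form the header row and first column.
#' @export
write_similarity <- function(mat, path) {
  dt <- data.table::data.table(sample_id = rownames(mat))
  dt <- cbind(dt, data.table::as.data.table(unclass(mat)[, , drop = FALSE]))
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}
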