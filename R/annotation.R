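#' Exact motif alignment against a reference sequence
#'
#' Every 1-based offset where the pattern matches contiguously, wildcards
#' free; overlapping matches are all reported. A sequence shorter than the
#' motif span yields an empty result (not an error).
#'
#' @param pattern motif string.
#' @param sequence amino-acid string.
#' @return integer vector of 1-based match offsets (possibly empty).
#' @export
#' @examples
#' exact_align("SLKPT", "GRGSRVGVPSLKPTLGGKAV") # 10
#' exact_align("AAAAA", "AAAAAA")               # 1 2
exact_align <- function(pattern, sequence) {
  if (nchar(sequence) < nchar(pattern)) return(integer(0))
  # zero-width lookahead reports overlapping matches
  m <- gregexpr(paste0("(?=", pattern, ")"), sequence, perl = TRUE)[[1]]
  if (m[1] == -1L) return(integer(0))
  as.integer(m)
}

#' Composition-preserving permutation test for a motif-sequence alignment
#'
#' The wildcard layout of the motif is held fixed while its fixed residues
#' are randomly re-ordered among the fixed positions (preserving amino-acid
#' composition). Orderings are sampled uniformly with replacement
#' `n_permutations` times; a permutation counts as a match when the permuted
#' motif has at least one exact match in the sequence. The empirical p-value
#' is `(matches + 1) / (n_permutations + 1)`, so it lies in
#' `[1/(N+1), 1]`; a motif whose fixed residues are all identical is
#' permutation-invariant and returns exactly 1.
#'
#' @param pattern motif string (run this test only for motifs with at least
#'   one exact match in `sequence`).
#' @param sequence amino-acid string held constant.
#' @param n_permutations number of sampled orderings (>= 1).
#' @param seed RNG seed; results are deterministic given it.
#' @return list with `n_permuted_matches` and `empirical_p`.
#' @export
permutation_alignment_test <- function(pattern, sequence, n_permutations = 10000L,
                                       seed = 1L) {
  if (n_permutations < 1L) abort_mimo("n_permutations must be >= 1", "mimo_validation_error")
  chars <- strsplit(pattern, "")[[1]]
  fixed_pos <- which(chars != ".")
  res <- chars[fixed_pos]
  nf <- length(res)
  n_matches <- with_seed(seed, {
    # sample orderings, then evaluate only the distinct permuted patterns and
    # weight by their multiplicities (<= nf! distinct patterns exist)
    perm_idx <- vapply(seq_len(n_permutations), function(i) {
      paste(sample.int(nf), collapse = ",")
    }, character(1))
    tab <- table(perm_idx)
    pats <- vapply(names(tab), function(key) {
      ord <- as.integer(strsplit(key, ",", fixed = TRUE)[[1]])
      p <- chars
      p[fixed_pos] <- res[ord]
      paste(p, collapse = "")
    }, character(1))
    upats <- unique(pats)
    hit <- vapply(upats, function(p) length(exact_align(p, sequence)) > 0L, logical(1))
    sum(as.integer(tab)[hit[match(pats, upats)]])
  })
  list(n_permuted_matches = n_matches,
       empirical_p = (n_matches + 1) / (n_permutations + 1))
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjustment with monotonicity enforcement; the order of the input
#' is preserved in the output and q >= p elementwise.
#'
#' @param p numeric vector of p-values in (0, 1].
#' @return adjusted q-values in the input order.
#' @export
fdr_adjust <- function(p) {
  if (!length(p)) return(numeric(0))
  if (any(p <= 0 | p > 1)) abort_mimo("p-values must lie in (0, 1]", "mimo_validation_error")
  stats::p.adjust(p, method = "BH")
}

#' Annotate selected motifs against a reference epitope database
#'
#' For every motif x pathogen-category epitope with at least one exact match,
#' computes the composition-preserving permutation p-value (sequence held
#' constant), then adjusts all tested pairs jointly with
#' Benjamini-Hochberg. Hits are sorted by q, then by decreasing match count.
#'
#' Per-pair seeds derive deterministically from `seed` so the result does not
#' depend on the order in which pairs are evaluated.
#'
#' @param patterns character vector of motif patterns (e.g.
#'   [selected_patterns()] output).
#' @param reference reference data.frame ([read_reference()] layout).
#' @param config a [pipeline_config()] (`n_permutations`).
#' @param seed master seed for the permutation null.
#' @param category which reference category to align against.
#' @return `data.frame` with columns `pattern`, `epitope_id`, `antigen`,
#'   `organism`, `offsets` (comma-joined, 1-based), `n_matches`,
#'   `n_permuted_matches`, `empirical_p`, `fdr_q`.
#' @export
annotate_motifs <- function(patterns, reference, config = pipeline_config(),
                            seed = config$rng_seed, category = "pathogen") {
  if (!nrow(reference)) abort_mimo("reference is empty", "mimo_validation_error")
  ref <- reference[reference$category == category, , drop = FALSE]
  rows <- list()
  for (pat in unique(patterns)) {
    for (r in seq_len(nrow(ref))) {
      offs <- exact_align(pat, ref$sequence[r])
      if (!length(offs)) next
      pt <- permutation_alignment_test(
        pat, ref$sequence[r], config$n_permutations,
        seed = derive_seed(seed, paste0(pat, "|", ref$epitope_id[r])))
      rows[[length(rows) + 1L]] <- data.frame(
        pattern = pat, epitope_id = ref$epitope_id[r],
        antigen = ref$antigen[r], organism = ref$organism[r],
        offsets = paste(offs, collapse = ","), n_matches = length(offs),
        n_permuted_matches = pt$n_permuted_matches,
        empirical_p = pt$empirical_p, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(pattern = character(0), epitope_id = character(0),
                      antigen = character(0), organism = character(0),
                      offsets = character(0), n_matches = integer(0),
                      n_permuted_matches = integer(0), empirical_p = numeric(0),
                      fdr_q = numeric(0), stringsAsFactors = FALSE))
  hits <- do.call(rbind, rows)
  hits$fdr_q <- fdr_adjust(hits$empirical_p)
  hits[order(hits$fdr_q, -hits$n_matches, hits$pattern), , drop = FALSE]
}

#' Cross-map pathogen hits to autoantigen mimicry
#'
#' Joins motifs that hit both a pathogen-category and an autoantigen-category
#' reference record into mimicry records carrying the autoantigen's cellular
#' location (NA when the reference lacks it).
#'
#' @param pathogen_hits [annotate_motifs()] output for the pathogen pass.
#' @param reference reference data.frame (autoantigen records are aligned
#'   here).
#' @param config,seed forwarded to the autoantigen [annotate_motifs()] pass.
#' @return `data.frame` with one row per (motif, pathogen epitope,
#'   autoantigen epitope) combination: `pattern`, `pathogen_epitope_id`,
#'   `pathogen_antigen`, `autoantigen_epitope_id`, `autoantigen`,
#'   `cellular_location`, `autoantigen_q`.
#' @export
crossmap_autoantigens <- function(pathogen_hits, reference,
                                  config = pipeline_config(), seed = config$rng_seed) {
  auto_hits <- annotate_motifs(unique(pathogen_hits$pattern), reference,
                               config, seed, category = "autoantigen")
  if (!nrow(auto_hits) || !nrow(pathogen_hits))
    return(data.frame(pattern = character(0), pathogen_epitope_id = character(0),
                      pathogen_antigen = character(0), autoantigen_epitope_id = character(0),
                      autoantigen = character(0), cellular_location = character(0),
                      autoantigen_q = numeric(0), stringsAsFactors = FALSE))
  loc <- stats::setNames(reference$cellular_location, reference$epitope_id)
  merged <- merge(
    data.frame(pattern = pathogen_hits$pattern,
               pathogen_epitope_id = pathogen_hits$epitope_id,
               pathogen_antigen = pathogen_hits$antigen, stringsAsFactors = FALSE),
    data.frame(pattern = auto_hits$pattern,
               autoantigen_epitope_id = auto_hits$epitope_id,
               autoantigen = auto_hits$antigen,
               autoantigen_q = auto_hits$fdr_q, stringsAsFactors = FALSE),
    by = "pattern")
  merged$cellular_location <- unname(loc[merged$autoantigen_epitope_id])
  merged
}
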