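#' Validate a gapped motif pattern
#'
#' A motif is a contiguous pattern over the 20 amino-acid letters plus the
#' wildcard `.`: span within the configured bounds (default 5-11), exactly
#' `n_fixed` (default 5) non-wildcard positions, and fixed residues at both
#' flanks (leading/trailing wildcards would create redundant equivalent
#' patterns).
#'
#' @param pattern motif string, e.g. `"S.KP..T"`.
#' @param span_min,span_max,n_fixed motif geometry constraints.
#' @return the pattern, invisibly, if valid; otherwise an error.
#' @export
validate_motif <- function(pattern, span_min = 5L, span_max = 11L, n_fixed = 5L) {
  span <- nchar(pattern)
  chars <- strsplit(pattern, "")[[1]]
  ok_chars <- all(chars %in% c(AA_ALPHABET, "."))
  if (!ok_chars) abort_mimo(paste0("motif has invalid characters: ", pattern), "mimo_motif_error")
  if (span < span_min || span > span_max)
    abort_mimo(sprintf("motif span %d outside [%d, %d]: %s", span, span_min, span_max, pattern),
               "mimo_motif_error")
  if (sum(chars != ".") != n_fixed)
    abort_mimo(sprintf("motif must have exactly %d fixed residues: %s", n_fixed, pattern),
               "mimo_motif_error")
  if (chars[1] == "." || chars[span] == ".")
    abort_mimo(paste0("motif must begin and end with a fixed residue: ", pattern), "mimo_motif_error")
  invisible(pattern)
}

motif_span <- function(pattern) nchar(pattern)
motif_fixed_residues <- function(pattern) {
  chars <- strsplit(pattern, "")[[1]]
  chars[chars != "."]
}

#' Match a motif within a peptide
#'
#' `TRUE` iff the pattern occurs as a contiguous window at any offset of the
#' peptide, wildcards matching any residue.
#'
#' @param pattern motif string (wildcard `.`).
#' @param peptides character vector of peptides.
#' @return logical vector along `peptides`.
#' @export
#' @examples
#' motif_matches("S.KPT", c("GGSAKPTAAAAA", "GGSLKAPTAAAA"))
motif_matches <- function(pattern, peptides) {
  grepl(pattern, peptides, perl = TRUE)
}

#' Upper-tail hypergeometric probability
#'
#' P(X >= k) for X hypergeometric: a group of `K` samples drawn without
#' replacement from `N` cohort samples of which `n` contain the motif.
#'
#' @param k matching samples observed in the target group.
#' @param K samples in the target group.
#' @param n matching samples overall.
#' @param N samples overall.
#' @return probability in (0, 1].
#' @export
hypergeometric_upper_tail <- function(k, K, n, N) {
  if (any(K > N | n > N | k > K | k > n | k < 0 | n < 0 | K < 0))
    abort_mimo("inconsistent hypergeometric margins", "mimo_validation_error")
  stats::phyper(k - 1, n, N - n, K, lower.tail = FALSE)
}

#' Motif presence in a sample
#'
#' A motif is present in a repertoire iff any peptide with count >=
#' `min_count` matches it.
#'
#' @param pattern motif string.
#' @param rep a [repertoire()].
#' @param min_count minimum read count establishing presence.
#' @return logical scalar.
#' @export
sample_presence <- function(pattern, rep, min_count = 1L) {
  if (min_count < 1L) abort_mimo("min_count must be >= 1", "mimo_validation_error")
  peps <- names(rep$counts)[rep$counts >= min_count]
  any(motif_matches(pattern, peps))
}

# Enumerate every (span, fixed-position layout) with exactly n_fixed fixed
# positions, fixed flanks, spans in [span_min, span_max]. Returns a list of
# integer vectors of relative fixed positions (1-based, first = 1, last = span).
motif_layouts <- function(span_min = 5L, span_max = 11L, n_fixed = 5L) {
  out <- list()
  for (span in span_min:span_max) {
    if (span == n_fixed) {
      out[[length(out) + 1L]] <- seq_len(span)
      next
    }
    interior <- 2:(span - 1L)
    if (length(interior) < n_fixed - 2L) next
    combs <- utils::combn(interior, n_fixed - 2L)
    for (c_i in seq_len(ncol(combs)))
      out[[length(out) + 1L]] <- c(1L, combs[, c_i], span)
  }
  out
}

# Instantiate, for a character vector of peptides, every candidate pattern:
# each layout at each admissible offset, residues copied from the peptide.
# Returns data.table(pep_idx, pattern).
instantiate_patterns <- function(peptides, span_min = 5L, span_max = 11L, n_fixed = 5L) {
  n <- length(peptides)
  # position-wise character matrix (12 x n)
  chars <- lapply(seq_len(PEPTIDE_LENGTH), function(i) substring(peptides, i, i))
  layouts <- motif_layouts(span_min, span_max, n_fixed)
  pat_list <- vector("list", 0L)
  idx_list <- vector("list", 0L)
  for (lay in layouts) {
    span <- lay[length(lay)]
    gaps <- strrep(".", diff(lay) - 1L)
    for (off in 0:(PEPTIDE_LENGTH - span)) {
      pos <- lay + off
      pats <- paste0(chars[[pos[1]]], gaps[1], chars[[pos[2]]], gaps[2],
                     chars[[pos[3]]], gaps[3], chars[[pos[4]]], gaps[4],
                     chars[[pos[5]]])
      pat_list[[length(pat_list) + 1L]] <- pats
      idx_list[[length(idx_list) + 1L]] <- seq_len(n)
    }
  }
  data.table::data.table(pep_idx = unlist(idx_list, use.names = FALSE),
                         pattern = unlist(pat_list, use.names = FALSE))
}

#' Discover group-discriminative gapped motifs
#'
#' Breadth-first discovery in the style of sequence-set pattern search:
#' candidate patterns are instantiated from observed peptides (every 5-11
#' span layout with exactly five fixed residues and fixed flanks, at every
#' admissible offset), so any scorable pattern matching at least one observed
#' peptide is enumerated exactly. Each candidate is scored by the upper-tail
#' hypergeometric probability of its sample-presence counts, in both
#' directions (case-enriched and control-enriched); candidates with identical
#' sample-match sets collapse to the shortest (then lexicographically
#' smallest) representative; results are ranked by `p_hyper`.
#'
#' Presence is assessed on the top `discover_top` most abundant peptides per
#' sample with count >= `min_count`; only patterns present in at least
#' `min_samples` samples are scored.
#'
#' @param case_repertoires,control_repertoires named lists of repertoires
#'   (>= 2 samples each).
#' @param config a [pipeline_config()]; geometry and search parameters are
#'   taken from it.
#' @return `data.frame` with columns `pattern`, `span`, `n_fixed`, `k`, `K`,
#'   `n`, `N`, `p_hyper`, `direction`, ranked by increasing `p_hyper`.
#' @export
discover_motifs <- function(case_repertoires, control_repertoires,
                            config = pipeline_config()) {
  if (length(case_repertoires) < 2L || length(control_repertoires) < 2L)
    abort_mimo("need at least two repertoires per group", "mimo_validation_error")
  reps <- c(case_repertoires, control_repertoires)
  grp <- c(rep("case", length(case_repertoires)),
           rep("control", length(control_repertoires)))
  # discovery peptide set: top discover_top by count (lexicographic ties)
  sp <- data.table::rbindlist(lapply(seq_along(reps), function(i) {
    r <- reps[[i]]
    cts <- r$counts[r$counts >= config$min_count]
    if (!length(cts)) return(NULL)
    keep <- top_k_profile(list(counts = cts), config$discover_top)
    data.table::data.table(samp = i, peptide = names(keep))
  }))
  if (!nrow(sp)) abort_mimo("no peptides pass min_count", "mimo_validation_error")
  upep <- sort(unique(sp$peptide))
  sp[, pep_idx := match(peptide, upep)]
  pats <- instantiate_patterns(upep, config$motif_span_min, config$motif_span_max,
                               config$motif_fixed)
  # presence pairs: (pattern, sample), unique
  pres <- unique(pats[sp, on = "pep_idx", allow.cartesian = TRUE][, .(pattern, samp)])
  is_case <- grp == "case"
  K <- sum(is_case); N <- length(reps)
  tab <- pres[, .(k = sum(is_case[samp]), n = .N), by = pattern]
  tab <- tab[n >= config$min_samples]
  if (!nrow(tab))
    return(data.frame(pattern = character(0), span = integer(0), n_fixed = integer(0),
                      k = integer(0), K = integer(0), n = integer(0), N = integer(0),
                      p_hyper = numeric(0), direction = character(0)))
  p_case <- hypergeometric_upper_tail(tab$k, K, tab$n, N)
  p_ctrl <- hypergeometric_upper_tail(tab$n - tab$k, N - K, tab$n, N)
  tab[, `:=`(p_hyper = pmin(p_case, p_ctrl),
             direction = ifelse(p_case <= p_ctrl, "case", "control"))]
  data.table::setorder(tab, p_hyper, pattern)
  # de-duplicate identical sample-match sets among the leading candidates
  short <- utils::head(tab, max(10L * config$max_candidates, 2000L))
  keys <- pres[pattern %in% short$pattern][order(samp),
               .(key = paste(samp, collapse = ",")), by = pattern]
  short <- keys[short, on = "pattern"]
  short[, len := nchar(pattern)]
  data.table::setorder(short, p_hyper, len, pattern)
  short <- short[!duplicated(key)]
  out <- utils::head(short, config$max_candidates)
  data.frame(pattern = out$pattern, span = nchar(out$pattern),
             n_fixed = config$motif_fixed,
             k = out$k, K = K, n = out$n, N = N,
             p_hyper = out$p_hyper, direction = out$direction,
             stringsAsFactors = FALSE)
}

#' Write a discovered-motif table as TSV
#'
#' @param motifs data.frame from [discover_motifs()].
#' @param path output path.
#' @export
write_motifs <- function(motifs, path) {
  data.table::fwrite(motifs, path, sep = "\t")
  invisible(path)
}
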