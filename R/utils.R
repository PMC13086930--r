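#' @importFrom data.table data.table as.data.table setDT setkey := .N .SD fread fwrite rbindlist setorder uniqueN
#' @importFrom stats phyper fisher.test wilcox.test cor t.test pt plogis rnorm runif rlnorm sd var p.adjust prcomp dist quantile median setNames binomial
#' @importFrom utils head tail
NULL

# canonical 20-letter amino-acid alphabet; anything else is rejected on load
AA_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

PEPTIDE_LENGTH <- 12L

is_valid_peptide <- function(x, len = PEPTIDE_LENGTH) {
  nchar(x) == len & grepl(paste0("^[", paste(AA_ALPHABET, collapse = ""), "]+$"), x)
}

is_valid_aa_string <- function(x) {
  nzchar(x) & grepl(paste0("^[", paste(AA_ALPHABET, collapse = ""), "]+$"), x)
}

#' Draw random amino-acid strings
#'
#' Uniform i.i.d. residues over the 20-letter alphabet. Used by the synthetic
#' cohort generator for background peptides and decoy reference epitopes.
#'
#' @param n number of strings
#' @param len string length (scalar or vector of length `n`)
#' @return character vector of length `n`
#' @keywords internal
random_aa_strings <- function(n, len = PEPTIDE_LENGTH) {
  if (n == 0L) return(character(0))
  len <- rep_len(len, n)
  vapply(len, function(l) paste(sample(AA_ALPHABET, l, replace = TRUE), collapse = ""),
         character(1))
}

# Deterministic per-stage seed derivation: a stage added later never perturbs
# the stream of another stage. Kept below 2^31.
derive_seed <- function(master_seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(master_seed) * 7919 + h) %% .Machine$integer.max)
}

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

abort_mimo <- function(msg, class) {
  stop(structure(class = c(class, "mimoprofile_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}
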