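#' Construct a sample repertoire
#'
#' A repertoire is one serum sample's immunoprofile: a map from displayed
#' 12-mer peptides to read counts. Zero-count entries are dropped; duplicate
#' peptides are summed.
#'
#' @param sample_id sample identifier.
#' @param counts named numeric/integer vector: names are 12-mer peptides over
#'   the 20-letter amino-acid alphabet, values are positive read counts.
#' @return object of class `mimo_repertoire` with fields `sample_id`,
#'   `counts` (named, positive) and `total_reads`.
#' @export
#' @examples
#' r <- repertoire("s1", c(ACDEFGHIKLMN = 5, ACDEFGHIKLMP = 3))
#' r$total_reads
repertoire <- function(sample_id, counts) {
  if (length(counts) == 0L) abort_mimo("repertoire must contain at least one peptide", "mimo_validation_error")
  peps <- toupper(names(counts))
  bad <- which(!is_valid_peptide(peps))
  if (length(bad)) {
    abort_mimo(paste0("sample ", sample_id, ": invalid peptide(s): ",
                      paste(utils::head(peps[bad], 5L), collapse = ", ")),
               "mimo_validation_error")
  }
  if (anyDuplicated(peps)) {
    counts <- tapply(as.numeric(counts), peps, sum)
    peps <- names(counts)
  }
  counts <- as.numeric(counts)
  names(counts) <- peps
  counts <- counts[counts > 0]
  if (length(counts) == 0L) abort_mimo("repertoire has no positive counts", "mimo_validation_error")
  counts <- counts[order(names(counts))]  # canonical order: row-order independent
  structure(list(sample_id = as.character(sample_id),
                 counts = counts,
                 total_reads = sum(counts)),
            class = "mimo_repertoire")
}

#' @export
print.mimo_repertoire <- function(x, ...) {
  cat("<mimo_repertoire>", x$sample_id, "-", length(x$counts), "peptides,",
      format(x$total_reads, big.mark = ","), "reads\n")
  invisible(x)
}

#' Read per-sample peptide count tables
#'
#' Reads a tab-separated table with columns `sample_id`, `peptide`, `count`
#' into one repertoire per sample. Duplicate (sample, peptide) rows are
#' summed; zero-count rows are dropped; peptides with any character outside
#' the 20 canonical amino acids are rejected with their row numbers.
#'
#' @param path TSV file path.
#' @return named list of [repertoire()] objects, keyed by `sample_id`.
#' @export
read_repertoires <- function(path) {
  if (!file.exists(path)) abort_mimo(paste0("file not found: ", path), "mimo_io_error")
  dt <- data.table::fread(path, sep = "\t", header = TRUE, colClasses = list(character = "peptide"))
  need <- c("sample_id", "peptide", "count")
  miss <- setdiff(need, names(dt))
  if (length(miss)) abort_mimo(paste0("missing column(s): ", paste(miss, collapse = ", ")), "mimo_schema_error")
  dt[, peptide := toupper(peptide)]
  bad <- which(!is_valid_peptide(dt$peptide))
  if (length(bad)) {
    abort_mimo(paste0("invalid peptide(s) at data row(s) ",
                      paste(utils::head(bad, 10L), collapse = ", "), ": ",
                      paste(utils::head(dt$peptide[bad], 5L), collapse = ", ")),
               "mimo_validation_error")
  }
  if (any(dt$count < 0)) abort_mimo("negative counts are not permitted", "mimo_validation_error")
  agg <- dt[, .(count = sum(count)), by = .(sample_id, peptide)][count > 0]
  ids <- sort(unique(agg$sample_id))
  reps <- lapply(ids, function(s) {
    sub <- agg[sample_id == s]
    repertoire(s, stats::setNames(sub$count, sub$peptide))
  })
  stats::setNames(reps, ids)
}

#' Write repertoires to a TSV table
#'
#' Inverse of [read_repertoires()]: rows are sorted by sample then peptide so
#' a write/read round trip is identity.
#'
#' @param repertoires named list of repertoires.
#' @param path output TSV path.
#' @export
write_repertoires <- function(repertoires, path) {
  dt <- data.table::rbindlist(lapply(repertoires, function(r) {
    data.table::data.table(sample_id = r$sample_id, peptide = names(r$counts), count = r$counts)
  }))
  data.table::setorder(dt, sample_id, peptide)
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}

#' Read sample metadata
#'
#' Reads the tab-separated sample sheet: required columns `sample_id`,
#' `subject_id`, `timepoint` (T1/T2), `group` (CPSNP/nonCPSNP/CTRL); optional
#' numeric `age` and `bmi` ("NA" for missing); any column named `sero_<virus>`
#' is parsed as a POS/NEG/B serostatus call for that virus.
#'
#' @param path TSV file path.
#' @return `data.frame` with one row per sample, serostatus columns retained
#'   under their `sero_` names.
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) abort_mimo(paste0("file not found: ", path), "mimo_io_error")
  dt <- data.table::fread(path, sep = "\t", header = TRUE, na.strings = "NA")
  need <- c("sample_id", "subject_id", "timepoint", "group")
  miss <- setdiff(need, names(dt))
  if (length(miss)) abort_mimo(paste0("missing column(s): ", paste(miss, collapse = ", ")), "mimo_schema_error")
  if (!all(dt$timepoint %in% c("T1", "T2")))
    abort_mimo("timepoint must be T1 or T2", "mimo_validation_error")
  if (!all(dt$group %in% c("CPSNP", "nonCPSNP", "CTRL")))
    abort_mimo("group must be one of CPSNP, nonCPSNP, CTRL", "mimo_validation_error")
  if (anyDuplicated(dt[, .(subject_id, timepoint)]))
    abort_mimo("duplicate (subject_id, timepoint) pairs", "mimo_validation_error")
  if (anyDuplicated(dt$sample_id))
    abort_mimo("duplicate sample_id", "mimo_validation_error")
  sero_cols <- grep("^sero_", names(dt), value = TRUE)
  for (sc in sero_cols) {
    v <- dt[[sc]]
    if (!all(is.na(v) | v %in% c("POS", "NEG", "B")))
      abort_mimo(paste0(sc, ": serostatus must be POS, NEG or B"), "mimo_validation_error")
  }
  as.data.frame(dt)
}

#' @rdname read_metadata
#' @param metadata metadata data.frame as returned by `read_metadata`.
#' @export
write_metadata <- function(metadata, path) {
  dt <- data.table::as.data.table(metadata)
  data.table::setorder(dt, sample_id)
  data.table::fwrite(dt, path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}

#' Read a reference epitope database
#'
#' Reads a tab-separated linear-epitope export with columns `epitope_id`,
#' `sequence`, `antigen`, `organism`, `category` (pathogen/autoantigen) and
#' optional `cellular_location`. Sequences are upper-cased and must be
#' non-empty amino-acid text of length >= 5.
#'
#' @param path TSV file path.
#' @return `data.frame` of validated reference records.
#' @export
read_reference <- function(path) {
  if (!file.exists(path)) abort_mimo(paste0("file not found: ", path), "mimo_io_error")
  dt <- data.table::fread(path, sep = "\t", header = TRUE, na.strings = "NA")
  need <- c("epitope_id", "sequence", "antigen", "organism", "category")
  miss <- setdiff(need, names(dt))
  if (length(miss)) abort_mimo(paste0("missing column(s): ", paste(miss, collapse = ", ")), "mimo_schema_error")
  dt[, sequence := toupper(sequence)]
  bad <- which(!is_valid_aa_string(dt$sequence) | nchar(dt$sequence) < 5L)
  if (length(bad))
    abort_mimo(paste0("invalid reference sequence(s) at row(s) ",
                      paste(utils::head(bad, 10L), collapse = ", ")), "mimo_validation_error")
  if (!all(dt$category %in% c("pathogen", "autoantigen")))
    abort_mimo("category must be pathogen or autoantigen", "mimo_validation_error")
  if (anyDuplicated(dt$epitope_id)) abort_mimo("duplicate epitope_id", "mimo_validation_error")
  if (!"cellular_location" %in% names(dt)) dt[, cellular_location := NA_character_]
  as.data.frame(dt)
}

#' @rdname read_reference
#' @param reference reference data.frame.
#' @export
write_reference <- function(reference, path) {
  dt <- data.table::as.data.table(reference)
  data.table::setorder(dt, epitope_id)
  data.table::fwrite(dt, path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}

#' Read reference antigens from FASTA
#'
#' Optional FASTA reader for reference sequences; the identifier line carries
#' `id|antigen|organism|category[|cellular_location]`.
#'
#' @param path FASTA file path.
#' @return reference `data.frame` in the same layout as [read_reference()].
#' @export
read_reference_fasta <- function(path) {
  if (!file.exists(path)) abort_mimo(paste0("file not found: ", path), "mimo_io_error")
  lines <- readLines(path)
  hdr <- grep("^>", lines)
  if (!length(hdr)) abort_mimo("no FASTA records found", "mimo_validation_error")
  ends <- c(hdr[-1] - 1L, length(lines))
  recs <- lapply(seq_along(hdr), function(i) {
    fields <- strsplit(sub("^>", "", lines[hdr[i]]), "|", fixed = TRUE)[[1]]
    if (length(fields) < 4L)
      abort_mimo("FASTA header must be id|antigen|organism|category[|location]", "mimo_schema_error")
    seqs <- paste(lines[(hdr[i] + 1L):ends[i]], collapse = "")
    data.table::data.table(epitope_id = fields[1], sequence = toupper(seqs),
                           antigen = fields[2], organism = fields[3],
                           category = fields[4],
                           cellular_location = if (length(fields) >= 5L) fields[5] else NA_character_)
  })
  out <- as.data.frame(data.table::rbindlist(recs))
  bad <- which(!is_valid_aa_string(out$sequence) | nchar(out$sequence) < 5L)
  if (length(bad)) abort_mimo("invalid FASTA sequence(s)", "mimo_validation_error")
  out
}
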