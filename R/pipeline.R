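#' Run the full mimotope profiling pipeline
#'
#' Orchestrates the stages end-to-end on a cohort: similarity QC ->
#' motif discovery -> feature selection -> reference annotation ->
#' seroreactivity quantification (with optional embedding/clustering) ->
#' classification. Inputs may be given as file paths (TSV dialects of the
#' IO module) or as in-memory objects; when `simulate` is a
#' [cohort_design()], the synthetic cohort is generated first. Every output
#' is written as plain TSV/JSON under `output_dir`, and a run manifest
#' records the config snapshot, input digests, per-stage seeds and output
#' files. All randomness derives from `config$rng_seed` via per-stage seeds,
#' so rerunning with the same config and inputs reproduces deterministic
#' outputs byte-identically.
#'
#' @param config a [pipeline_config()].
#' @param output_dir directory for stage outputs (created if needed).
#' @param repertoires,metadata,reference in-memory inputs or file paths;
#'   ignored when `simulate` is given.
#' @param simulate optional [cohort_design()]; when supplied the cohort is
#'   generated and written to `output_dir` first.
#' @param case_group label treated as the positive class (default "CPSNP").
#' @param embed run the t-SNE/DBSCAN stage when enough motifs were annotated
#'   (it is skipped otherwise).
#' @return list of class `mimo_manifest`; component `results` holds the
#'   in-memory stage outputs.
#' @export
run_pipeline <- function(config, output_dir,
                         repertoires = NULL, metadata = NULL, reference = NULL,
                         simulate = NULL, case_group = "CPSNP", embed = FALSE) {
  validate_config(config)
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  t0 <- Sys.time()
  stages <- character(0)
  outputs <- character(0)
  seeds <- list()
  results <- list()
  current_stage <- NA_character_
  begin_stage <- function(stage) {
    stages <<- c(stages, stage)
    seeds[[stage]] <<- derive_seed(config$rng_seed, stage)
    current_stage <<- stage
    message(sprintf("[%s] stage %s", format(Sys.time(), "%H:%M:%S"), stage))
  }
  emit <- function(name) outputs <<- c(outputs, name)
  fail <- function(e) abort_mimo(paste0("stage '", current_stage, "' failed: ",
                                        conditionMessage(e)), "mimo_stage_error")

  if (!is.null(simulate)) {
    begin_stage("simulate")
    tryCatch({
      sim_design <- simulate
      sim_design$rng_seed <- seeds[["simulate"]]
      cohort <- generate_cohort(sim_design)
      repertoires <- cohort$repertoires
      metadata <- cohort$metadata
      reference <- cohort$reference
      results$ground_truth <- cohort$ground_truth
      write_repertoires(repertoires, file.path(output_dir, "repertoires.tsv"))
      write_metadata(metadata, file.path(output_dir, "metadata.tsv"))
      write_reference(reference, file.path(output_dir, "reference.tsv"))
      write_ground_truth(cohort$ground_truth, file.path(output_dir, "ground_truth.tsv"))
      emit("repertoires.tsv"); emit("metadata.tsv"); emit("reference.tsv")
      emit("ground_truth.tsv")
    }, error = fail)
  }
  if (is.character(repertoires)) repertoires <- read_repertoires(repertoires)
  if (is.character(metadata)) metadata <- read_metadata(metadata)
  if (is.character(reference)) reference <- read_reference(reference)
  if (is.null(repertoires) || is.null(metadata) || is.null(reference))
    abort_mimo("repertoires, metadata and reference are required (or pass simulate=)",
               "mimo_validation_error")
  input_digest <- list(
    n_samples = length(repertoires),
    n_reference = nrow(reference),
    metadata_digest = unname(tools::md5sum(
      write_metadata(metadata, file.path(output_dir, ".metadata_snapshot.tsv")))))

  begin_stage("similarity")
  tryCatch({
    sim <- similarity_matrix(repertoires, config$top_k)
    summ <- suppressMessages(paired_unpaired_summary(sim, metadata))
    excl <- qc_exclude(sim, metadata, config$csi_pair_min)
    write_similarity(sim, file.path(output_dir, "similarity_matrix.tsv"))
    data.table::fwrite(excl, file.path(output_dir, "qc_exclusions.tsv"), sep = "\t")
    emit("similarity_matrix.tsv"); emit("qc_exclusions.tsv")
    results$similarity <- sim
    results$pair_summary <- summ
    results$exclusions <- excl
    keep <- setdiff(names(repertoires), excl$sample_id)
    repertoires <- repertoires[keep]
    metadata <- metadata[metadata$sample_id %in% keep, , drop = FALSE]
  }, error = fail)

  begin_stage("discover")
  tryCatch({
    case_ids <- metadata$sample_id[metadata$group == case_group]
    ctrl_ids <- metadata$sample_id[metadata$group == "nonCPSNP"]
    results$motifs <- discover_motifs(repertoires[case_ids], repertoires[ctrl_ids], config)
    write_motifs(results$motifs, file.path(output_dir, "motifs.tsv"))
    emit("motifs.tsv")
  }, error = fail)

  begin_stage("select")
  tryCatch({
    motifs <- results$motifs
    if (!nrow(motifs)) abort_mimo("no candidate motifs discovered", "mimo_validation_error")
    fm <- epitope_feature_matrix(repertoires, motifs$pattern, config)
    results$feature_matrix <- fm
    results$selection <- select_features(fm, metadata, case_group = case_group,
                                         config = config)
    data.table::fwrite(results$selection, file.path(output_dir, "selection.tsv"), sep = "\t")
    emit("selection.tsv")
  }, error = fail)

  begin_stage("annotate")
  tryCatch({
    pats <- selected_patterns(results$selection)
    results$hits <- annotate_motifs(pats, reference, config, seed = seeds[["annotate"]])
    results$mimicry <- crossmap_autoantigens(results$hits, reference, config,
                                             seed = seeds[["annotate"]])
    data.table::fwrite(results$hits, file.path(output_dir, "annotation_hits.tsv"), sep = "\t")
    data.table::fwrite(results$mimicry, file.path(output_dir, "mimicry.tsv"), sep = "\t")
    emit("annotation_hits.tsv"); emit("mimicry.tsv")
  }, error = fail)

  begin_stage("quantify")
  tryCatch({
    hits <- results$hits
    annotated <- unique(hits$pattern[hits$fdr_q < 0.05])
    if (!length(annotated)) annotated <- unique(hits$pattern)
    if (length(annotated)) {
      fm <- results$feature_matrix[annotated, , drop = FALSE]
      summ <- group_response_summary(fm, metadata)
      results$quantification <- summ
      data.table::fwrite(summ$per_sample, file.path(output_dir, "seroreactivity.tsv"), sep = "\t")
      data.table::fwrite(summ$group_tests, file.path(output_dir, "group_tests.tsv"), sep = "\t")
      emit("seroreactivity.tsv"); emit("group_tests.tsv")
      if (embed && nrow(fm) >= 3 * config$tsne_perplexity) {
        ec <- embed_and_cluster(fm, config, seed = seeds[["quantify"]])
        results$clusters <- ec
        data.table::fwrite(data.frame(pattern = rownames(fm), cluster = ec$cluster,
                                      x = ec$coords[, 1], y = ec$coords[, 2]),
                           file.path(output_dir, "clusters.tsv"), sep = "\t")
        emit("clusters.tsv")
      }
    }
  }, error = fail)

  begin_stage("classify")
  tryCatch({
    hits <- results$hits
    annotated <- unique(hits$pattern[hits$fdr_q < 0.05])
    if (!length(annotated)) {
      results["classifier"] <- list(NULL)
      message("classify: no annotated motifs below q < 0.05; stage skipped")
    } else {
      t1 <- metadata$sample_id[metadata$timepoint == "T1"]
      Xm <- t(results$feature_matrix[annotated, t1, drop = FALSE])
      yl <- as.integer(metadata$group[match(t1, metadata$sample_id)] == case_group)
      results$classifier <- classifier_report(Xm, yl, config,
                                              seed = seeds[["classify"]])
      cr <- results$classifier
      jsonlite::write_json(
        list(feature_names = cr$feature_names,
             coefficients = as.list(cr$coefficients),
             auc = cr$auc, cv_auc = cr$cv_auc, permutation_p = cr$permutation_p,
             sensitivity = cr$sensitivity, specificity = cr$specificity,
             balanced_accuracy = cr$balanced_accuracy, cutpoint = cr$cutpoint),
        file.path(output_dir, "classifier.json"), auto_unbox = TRUE, digits = NA)
      emit("classifier.json")
    }
  }, error = fail)

  manifest <- structure(list(
    config = unclass(config),
    input_digest = input_digest,
    stages = stages,
    stage_seeds = seeds,
    outputs = outputs,
    started = format(t0), finished = format(Sys.time()),
    results = results), class = "mimo_manifest")
  jsonlite::write_json(manifest[c("config", "input_digest", "stages",
                                  "stage_seeds", "outputs", "started", "finished")],
                       file.path(output_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  manifest
}

#' Human-readable run report
#'
#' Renders a completed manifest as markdown: excluded samples, selected
#' motif counts, top annotation hits, and classifier metrics. An incomplete
#' manifest yields a partial report with warnings.
#'
#' @param manifest a `mimo_manifest` from [run_pipeline()].
#' @return character scalar of markdown.
#' @export
report <- function(manifest) {
  r <- manifest$results
  lines <- c("# Mimotope profiling run report", "")
  lines <- c(lines, "## Similarity QC", "")
  if (!is.null(r$pair_summary)) {
    lines <- c(lines, sprintf(
      "- mean paired CSI %.3f over %d pairs; mean unpaired CSI %.3f over %d pairs",
      r$pair_summary$mean_paired, r$pair_summary$n_paired,
      r$pair_summary$mean_unpaired, r$pair_summary$n_unpaired))
    lines <- c(lines, if (nrow(r$exclusions))
      sprintf("- excluded samples: %s", paste(r$exclusions$sample_id, collapse = ", "))
      else "- no samples excluded")
  } else {
    warning("manifest lacks similarity results")
    lines <- c(lines, "- (stage missing)")
  }
  lines <- c(lines, "", "## Motif discovery and selection", "")
  if (!is.null(r$motifs))
    lines <- c(lines, sprintf("- %d candidate motifs discovered", nrow(r$motifs)))
  if (!is.null(r$selection))
    lines <- c(lines, sprintf("- %d motifs selected (t-test + Youden thresholds)",
                              length(selected_patterns(r$selection))))
  lines <- c(lines, "", "## Reference annotation", "")
  if (!is.null(r$hits) && nrow(r$hits)) {
    top <- utils::head(r$hits, 5L)
    lines <- c(lines, "| pattern | organism | antigen | q |", "|---|---|---|---|",
               sprintf("| %s | %s | %s | %.3g |", top$pattern, top$organism,
                       top$antigen, top$fdr_q))
  } else lines <- c(lines, "- no annotation hits")
  lines <- c(lines, "", "## Classifier", "")
  if (!is.null(r$classifier)) {
    cr <- r$classifier
    lines <- c(lines, sprintf(
      "- AUC %.3f, cv-AUC %.3f, permutation p %.4g, sensitivity %.2f, specificity %.2f, balanced accuracy %.3f",
      cr$auc, cr$cv_auc, cr$permutation_p, cr$sensitivity, cr$specificity,
      cr$balanced_accuracy))
  } else lines <- c(lines, "- skipped (no annotated motifs)")
  paste(lines, collapse = "\n")
}
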