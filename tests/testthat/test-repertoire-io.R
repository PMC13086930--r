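test_that("repertoire tables load, validate and aggregate duplicates", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample_id\tpeptide\tcount",
               "s1\tACDEFGHIKLMN\t5",
               "s1\tACDEFGHIKLMP\t3",
               "s1\tacdefghiklmq\t1",
               "s2\tACDEFGHIKLMN\t2",
               "s2\tACDEFGHIKLMN\t3"), tf)
  reps <- read_repertoires(tf)
  expect_named(reps, c("s1", "s2"))
  expect_length(reps$s1$counts, 3L)
  expect_equal(reps$s1$total_reads, 9)
  # lower case is normalized on load
  expect_true("ACDEFGHIKLMQ" %in% names(reps$s1$counts))
  # duplicate (sample, peptide) rows are summed
  expect_equal(unname(reps$s2$counts["ACDEFGHIKLMN"]), 5)
})

test_that("malformed repertoire input is rejected with informative errors", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample_id\tpeptide", "s1\tACDEFGHIKLMN"), tf)
  expect_error(read_repertoires(tf), "missing column", class = "mimo_schema_error")
  # X is not part of the canonical alphabet and must name the offending row
  writeLines(c("sample_id\tpeptide\tcount", "s1\tACDEFGHIKLMN\t1",
               "s1\tACDEFGHIKLMX\t2"), tf)
  expect_error(read_repertoires(tf), "row\\(s\\) 2", class = "mimo_validation_error")
  # wrong length
  writeLines(c("sample_id\tpeptide\tcount", "s1\tACDEF\t1"), tf)
  expect_error(read_repertoires(tf), class = "mimo_validation_error")
})

test_that("repertoire IO round-trips and is row-order independent", {
  reps <- list(
    a = fix_repertoire("a", fix_peptides(4), c(5, 4, 3, 2)),
    b = fix_repertoire("b", fix_peptides(3), c(9, 1, 1)))
  tf <- withr::local_tempfile(fileext = ".tsv")
  write_repertoires(reps, tf)
  back <- read_repertoires(tf)
  expect_equal(lapply(back, function(r) r$counts[order(names(r$counts))]),
               lapply(reps, function(r) r$counts[order(names(r$counts))]))
  # permuting rows yields identical parsed structures
  lines <- readLines(tf)
  shuf <- c(lines[1], sample(lines[-1]))
  tf2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(shuf, tf2)
  expect_equal(read_repertoires(tf2), back)
})

test_that("metadata parsing enforces subject/timepoint uniqueness and serostatus levels", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample_id\tsubject_id\ttimepoint\tgroup\tage\tsero_HSV2",
               "s1\tp1\tT1\tCPSNP\t55\tPOS",
               "s2\tp1\tT2\tCPSNP\tNA\tB",
               "s3\tp2\tT1\tnonCPSNP\t60\tNEG",
               "s4\tp2\tT2\tnonCPSNP\t66\tNEG"), tf)
  md <- read_metadata(tf)
  expect_equal(nrow(md), 4L)
  expect_equal(length(unique(md$subject_id)), 2L)
  expect_equal(md$sero_HSV2[md$sample_id == "s2"], "B")
  expect_true(is.na(md$age[md$sample_id == "s2"]))
  # round trip
  tf2 <- withr::local_tempfile(fileext = ".tsv")
  write_metadata(md, tf2)
  expect_equal(read_metadata(tf2), md[order(md$sample_id), ], ignore_attr = TRUE)
  # two T1 rows for the same subject violate the design invariant
  writeLines(c("sample_id\tsubject_id\ttimepoint\tgroup",
               "s1\tp1\tT1\tCPSNP", "s2\tp1\tT1\tCPSNP"), tf)
  expect_error(read_metadata(tf), "duplicate", class = "mimo_validation_error")
})

test_that("reference databases load with upper-casing and category checks", {
  ref <- read_reference(system.file("extdata", "example_reference.tsv",
                                    package = "mimoprofile"))
  expect_true(all(c("GRGSRVGVPSLKPTLGGKAV", "PKRLRLPHIRDD") %in% ref$sequence))
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("epitope_id\tsequence\tantigen\torganism\tcategory",
               "e1\tslkptlggk\tpp150\tCMV\tpathogen"), tf)
  expect_equal(read_reference(tf)$sequence, "SLKPTLGGK")
  writeLines(c("epitope_id\tsequence\tantigen\torganism\tcategory",
               "e1\t\tpp150\tCMV\tpathogen"), tf)
  expect_error(read_reference(tf), class = "mimo_validation_error")
  writeLines(c("epitope_id\tsequence\tantigen\torganism\tcategory",
               "e1\tSLKPTLGGK\tpp150\tCMV\tsomething"), tf)
  expect_error(read_reference(tf), "category", class = "mimo_validation_error")
})

test_that("FASTA reference reader parses annotated headers", {
  tf <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">e1|pp150|CMV|pathogen", "GRGSRVGVPS", "LKPTLGGKAV",
               ">e2|colVI|Homo sapiens|autoantigen|Secreted", "MAPKRLRLPH"), tf)
  ref <- read_reference_fasta(tf)
  expect_equal(ref$sequence[1], "GRGSRVGVPSLKPTLGGKAV")
  expect_equal(ref$cellular_location, c(NA, "Secreted"))
})

test_that("configuration defaults match the published constants and round-trip via YAML", {
  cfg <- pipeline_config()
  expect_equal(cfg$top_k, 5000L)
  expect_equal(cfg$csi_pair_min, 0.70)
  expect_equal(cfg$normalization_total, 3e6)
  expect_equal(cfg$select_p_max, 0.05)
  expect_equal(cfg$select_youden_min, 0.25)
  expect_equal(cfg$n_permutations, 10000L)
  expect_equal(c(cfg$tsne_dims, cfg$tsne_perplexity, cfg$tsne_max_iter), c(2, 15, 500))
  expect_equal(c(cfg$dbscan_epsilon, cfg$dbscan_min_pts), c(2, 10))
  expect_equal(cfg$cv_folds, 5L)
  expect_equal(c(cfg$motif_span_min, cfg$motif_span_max, cfg$motif_fixed), c(5L, 11L, 5L))
  tf <- withr::local_tempfile(fileext = ".yaml")
  write_config(cfg, tf)
  expect_equal(read_config(tf), cfg)
  expect_error(pipeline_config(csi_pair_min = 1.01), class = "mimo_config_error")
  expect_error(pipeline_config(motif_fixed = 6, motif_span_min = 5), class = "mimo_config_error")
})
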