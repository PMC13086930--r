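test_that("top_k_profile keeps the k most abundant peptides with lexicographic tie-break", {
  r <- fix_repertoire("s", c("DDDDDDDDDDDD", "CCCCCCCCCCCC", "AAAAAAAAAAAA"),
                      c(5, 3, 3))
  # tie at rank 2 between C... (3) and A... (3): lexicographically smaller wins
  expect_equal(names(top_k_profile(r, 2L)), c("DDDDDDDDDDDD", "AAAAAAAAAAAA"))
  expect_equal(unname(top_k_profile(r, 2L)), c(5, 3))
  # k beyond the repertoire returns everything
  expect_length(top_k_profile(r, 5000L), 3L)
  expect_error(top_k_profile(r, 0L), class = "mimo_validation_error")
})

test_that("cosine similarity follows the normalized scalar product", {
  a <- c(p1 = 1, p2 = 2, p3 = 2)
  b <- c(p1 = 2, p2 = 1, p3 = 2)
  expect_equal(cosine_similarity(a, b), 8 / 9)
  expect_equal(cosine_similarity(a, a), 1)
  expect_equal(cosine_similarity(a, 7 * a), 1)            # proportional
  expect_equal(cosine_similarity(a, c(q1 = 3, q2 = 1)), 0) # disjoint supports
  # symmetry and scale invariance on random vectors
  set.seed(1)
  for (i in 1:10) {
    x <- stats::setNames(runif(6), paste0("p", 1:6))
    y <- stats::setNames(runif(6), paste0("p", sample(1:9, 6)))
    expect_equal(cosine_similarity(x, y), cosine_similarity(y, x))
    expect_equal(cosine_similarity(3.7 * x, y), cosine_similarity(x, y))
    expect_gte(cosine_similarity(x, y), 0)
    expect_lte(cosine_similarity(x, y), 1)
  }
  expect_error(cosine_similarity(c(p1 = 0), a), class = "mimo_validation_error")
})

test_that("similarity matrices are symmetric, unit-diagonal and structure-faithful", {
  peps <- fix_peptides(12)
  same1 <- fix_repertoire("a", peps[1:4], c(4, 3, 2, 1))
  same2 <- fix_repertoire("b", peps[1:4], c(8, 6, 4, 2))  # proportional to a
  disj <- fix_repertoire("c", peps[5:8], c(1, 1, 1, 1))
  S <- similarity_matrix(list(a = same1, b = same2, c = disj), 10L)
  expect_equal(dim(S), c(3L, 3L))
  expect_equal(unname(diag(S)), rep(1, 3))
  expect_equal(unclass(S), t(unclass(S)), ignore_attr = TRUE)
  expect_equal(S["a", "b"], 1)
  expect_equal(S["a", "c"], 0)
  # mutually disjoint repertoires give the identity matrix
  S2 <- similarity_matrix(list(a = fix_repertoire("a", peps[1:2], c(2, 1)),
                               b = fix_repertoire("b", peps[3:4], c(2, 1)),
                               c = fix_repertoire("c", peps[5:6], c(2, 1))), 10L)
  expect_equal(unclass(S2), diag(3), ignore_attr = TRUE)
  expect_error(similarity_matrix(list(a = same1), 10L), class = "mimo_validation_error")
})

test_that("paired/unpaired bookkeeping matches two-timepoint combinatorics", {
  # 59 subjects x 2 timepoints: 59 paired pairs and C(118,2)-59 = 6844 others
  md <- fix_two_timepoint_metadata(59L)
  set.seed(7)
  n <- nrow(md)
  M <- matrix(runif(n * n), n, n)
  M <- (M + t(M)) / 2; diag(M) <- 1
  dimnames(M) <- list(md$sample_id, md$sample_id)
  su <- paired_unpaired_summary(M, md)
  expect_equal(su$n_paired, 59L)
  expect_equal(su$n_unpaired, 6844L)
  expect_equal(su$n_paired + su$n_unpaired, choose(n, 2))
  # identical-profile subjects give mean paired CSI 1
  peps <- fix_peptides(6)
  reps <- list(
    S1_T1 = fix_repertoire("S1_T1", peps[1:3], c(3, 2, 1)),
    S1_T2 = fix_repertoire("S1_T2", peps[1:3], c(3, 2, 1)),
    S2_T1 = fix_repertoire("S2_T1", peps[4:6], c(5, 1, 1)),
    S2_T2 = fix_repertoire("S2_T2", peps[4:6], c(5, 1, 1)))
  md2 <- fix_two_timepoint_metadata(2L)
  md2$sample_id <- c("S1_T1", "S2_T1", "S1_T2", "S2_T2")
  md2$subject_id <- c("S1", "S2", "S1", "S2")
  su2 <- paired_unpaired_summary(similarity_matrix(reps, 10L), md2)
  expect_equal(su2$mean_paired, 1)
  # a subject with a single sample is logged and excluded from the paired set
  md3 <- md2[1:3, ]
  expect_message(paired_unpaired_summary(similarity_matrix(reps[1:3], 10L), md3),
                 "single sample")
})

test_that("QC exclusion flags both samples of low-CSI subjects only", {
  md <- fix_two_timepoint_metadata(3L)
  ids <- md$sample_id
  M <- diag(6); dimnames(M) <- list(ids, ids)
  M["S001_T1", "S001_T2"] <- M["S001_T2", "S001_T1"] <- 0.9
  M["S002_T1", "S002_T2"] <- M["S002_T2", "S002_T1"] <- 0.5
  M["S003_T1", "S003_T2"] <- M["S003_T2", "S003_T1"] <- 0.71
  ex <- qc_exclude(M, md, 0.70)
  expect_setequal(ex$sample_id, c("S002_T1", "S002_T2"))
  expect_match(ex$reason[1], "below 0.70")
  # all pairs above the floor: nothing excluded
  M["S002_T1", "S002_T2"] <- M["S002_T2", "S002_T1"] <- 0.95
  expect_equal(nrow(qc_exclude(M, md, 0.70)), 0L)
  expect_error(qc_exclude(M, md, 1.5), class = "mimo_validation_error")
})

test_that("similarity matrix TSV output round-trips numerically", {
  peps <- fix_peptides(8)
  reps <- list(a = fix_repertoire("a", peps[1:5], c(9, 5, 3, 2, 1)),
               b = fix_repertoire("b", peps[3:7], c(4, 4, 2, 2, 1)))
  S <- similarity_matrix(reps, 5L)
  tf <- withr::local_tempfile(fileext = ".tsv")
  write_similarity(S, tf)
  back <- as.data.frame(data.table::fread(tf))
  expect_equal(back$sample_id, rownames(S))
  expect_equal(as.matrix(back[, -1]), unclass(S), ignore_attr = TRUE)
})
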