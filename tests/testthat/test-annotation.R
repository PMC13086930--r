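test_that("exact alignment reports all 1-based offsets including overlaps", {
  expect_equal(exact_align("SLKPT", "GRGSRVGVPSLKPTLGGKAV"), 10L)
  expect_equal(exact_align("AAAAA", "AAAAAA"), c(1L, 2L))
  expect_equal(exact_align("SLKPT", "TPKLS"), integer(0))
  expect_equal(exact_align("SLKPT", "SLK"), integer(0))  # sequence shorter than span
  expect_equal(exact_align("S.KPT", "SAKPTGGGGGGG"), 1L)  # wildcard position free
  expect_equal(exact_align("P.C", "PACQPCCPVC"), c(1L, 5L, 8L))
})

test_that("permutation test honours its formula bounds and invariances", {
  # permutation-invariant motif: every ordering matches wherever the original does
  res <- permutation_alignment_test("AAAAA", "GGAAAAAGG", n_permutations = 500L, seed = 1L)
  expect_equal(res$empirical_p, 1)
  expect_equal(res$n_permuted_matches, 500L)
  # no permuted variant matches: exact formula floor 1/(N+1)
  res2 <- permutation_alignment_test("ACDEF", "GGGGGGGGGGGG", n_permutations = 500L, seed = 1L)
  expect_equal(res2$n_permuted_matches, 0L)
  expect_equal(res2$empirical_p, 1 / 501)
  expect_error(permutation_alignment_test("ACDEF", "ACDEFG", n_permutations = 0L),
               class = "mimo_validation_error")
  # bounds across fuzzed inputs
  set.seed(5)
  for (i in 1:10) {
    pat <- paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], 5), collapse = "")
    seqs <- paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], 15, TRUE), collapse = "")
    r <- permutation_alignment_test(pat, seqs, n_permutations = 200L, seed = i)
    expect_gte(r$empirical_p, 1 / 201)
    expect_lte(r$empirical_p, 1)
  }
})

test_that("sampled permutation matches agree with the exact 120-ordering null", {
  # five distinct fixed residues: exactly 120 distinct orderings
  cases <- list(
    list(pat = "ACDEF", seqs = "ACDEFCADEF"),           # >= 2 matching orderings
    list(pat = "KLMNP", seqs = "GGKLMNPGGGG"),          # identity only
    list(pat = "A.CDEF", seqs = "AGCDEFQQFEDCHA"))      # gapped layout preserved
  N <- 4000L
  for (cs in cases) {
    q <- enum_perm_match_fraction(cs$pat, cs$seqs)
    r <- permutation_alignment_test(cs$pat, cs$seqs, n_permutations = N, seed = 99L)
    se <- sqrt(q * (1 - q) / N)
    expect_lt(abs(r$n_permuted_matches / N - q), 3 * se + 1e-9,
              label = paste("pattern", cs$pat))
  }
})

test_that("BH adjustment reproduces hand computations and its invariants", {
  expect_equal(fdr_adjust(0.03), 0.03)
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(fdr_adjust(c(0.2, 0.2, 0.2)), c(0.2, 0.2, 0.2))
  expect_equal(fdr_adjust(numeric(0)), numeric(0))
  # hand BH oracle: p(i) * m / i then cumulative minimum from the largest p
  hand_bh <- function(p) {
    o <- order(p); m <- length(p)
    q <- rev(cummin(rev(p[o] * m / seq_len(m))))
    out <- numeric(m); out[o] <- pmin(q, 1)
    out
  }
  p <- c(0.04, 0.001, 0.3, 0.03)
  expect_equal(fdr_adjust(p), hand_bh(p))
  set.seed(3)
  for (i in 1:5) {
    ps <- runif(8)
    q <- fdr_adjust(ps)
    expect_true(all(q >= ps))
    expect_false(is.unsorted(q[order(ps)]))  # monotone over sorted input
    # order preservation
    o <- sample(8)
    expect_equal(fdr_adjust(ps[o]), q[o])
  }
  expect_error(fdr_adjust(c(0.1, 0)), class = "mimo_validation_error")
})

test_that("annotation links planted motifs to their source epitopes with small q", {
  co <- generate_cohort(fix_small_design(seed = 41L, n_planted = 2L))
  cfg <- fix_small_config(n_permutations = 2000L)
  gt <- co$ground_truth$planted_motifs
  hits <- annotate_motifs(gt$pattern, co$reference, cfg, seed = 7L)
  for (i in seq_len(nrow(gt))) {
    hit <- hits[hits$pattern == gt$pattern[i] & hits$epitope_id == gt$epitope_id[i], ]
    expect_equal(nrow(hit), 1L)
    expect_lt(hit$fdr_q, 0.05)
  }
  # a motif with zero matches anywhere emits no hits
  hits2 <- annotate_motifs("WWWWW", co$reference, cfg, seed = 7L)
  expect_equal(nrow(hits2), 0L)
  # a permutation-invariant motif matching a reference gets q = 1
  ref1 <- data.frame(epitope_id = "E1", sequence = "GGGAAAAAGGG", antigen = "x",
                     organism = "y", category = "pathogen",
                     cellular_location = NA_character_)
  hits3 <- annotate_motifs("AAAAA", ref1, cfg, seed = 7L)
  expect_equal(hits3$empirical_p, 1)
})

test_that("autoantigen cross-mapping joins pathogen and autoantigen hits", {
  co <- generate_cohort(fix_small_design(seed = 43L, n_planted = 2L))
  cfg <- fix_small_config(n_permutations = 1000L)
  gt <- co$ground_truth$planted_motifs
  hits <- annotate_motifs(gt$pattern, co$reference, cfg, seed = 3L)
  mim <- crossmap_autoantigens(hits, co$reference, cfg, seed = 3L)
  # the generator embeds planted motif 1 in a mock human antigen
  expect_true(gt$pattern[1] %in% mim$pattern)
  rec <- mim[mim$pattern == gt$pattern[1] & mim$autoantigen_epitope_id == "EPI_AUTO_MIMIC", ]
  expect_gt(nrow(rec), 0L)
  expect_equal(unique(rec$cellular_location), "Cell membrane")
  # motif 2 has no autoantigen counterpart
  expect_false(gt$pattern[2] %in% mim$pattern)
})
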