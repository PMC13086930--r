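test_that("ROC AUC equals positive-negative pair counting", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.2, 0.1), c(1, 0, 1, 0)), 0.75)
  expect_equal(roc_auc(c(4, 3, 2, 1), c(1, 1, 0, 0)), 1)
  expect_equal(roc_auc(rep(0.5, 6), c(1, 1, 1, 0, 0, 0)), 0.5)  # all ties
  set.seed(23)
  for (i in 1:15) {
    n <- sample(4:12, 1)
    y <- c(0, 1, rbinom(n - 2, 1, 0.5))
    s <- sample(5, n, replace = TRUE)  # forced ties
    expect_equal(roc_auc(s, y), enum_auc(s, y))
    # strictly monotone transform invariance
    expect_equal(roc_auc(exp(s), y), roc_auc(s, y))
  }
  expect_error(roc_auc(1:3, c(1, 1, 1)), class = "mimo_validation_error")
})

test_that("logistic fit recovers closed-form odds and flags separation", {
  # grouped two-point structure: P(y|x=0) = 1/3, P(y|x=1) = 2/3
  X <- matrix(c(0, 0, 0, 1, 1, 1), ncol = 1)
  y <- c(1, 0, 0, 1, 1, 0)
  fit <- fit_logistic(X, y)
  expect_equal(unname(fit$coefficients[1]), stats::qlogis(1 / 3), tolerance = 1e-5)
  expect_equal(unname(fit$coefficients[2]),
               stats::qlogis(2 / 3) - stats::qlogis(1 / 3), tolerance = 1e-5)
  expect_false(fit$separation)
  # a feature equal to the label: separable, finite ridge solution, AUC 1
  Xs <- matrix(c(0, 0, 0, 1, 1, 1), ncol = 1)
  ys <- c(0, 0, 0, 1, 1, 1)
  expect_warning(fits <- fit_logistic(Xs, ys), "separation")
  expect_true(fits$separation)
  expect_true(all(is.finite(fits$coefficients)))
  expect_equal(roc_auc(fits$fitted, ys), 1)
  expect_error(fit_logistic(Xs, rep(1, 6)), class = "mimo_validation_error")
})

test_that("operating point reuses the Youden criterion and reports balanced accuracy", {
  scores <- c(0.9, 0.8, 0.7, 0.3, 0.2, 0.1)
  labels <- c(1, 1, 1, 0, 0, 0)
  op <- youden_operating_point(scores, labels)
  expect_equal(op$sensitivity, 1)
  expect_equal(op$specificity, 1)
  expect_equal(op$balanced_accuracy, 1)
  set.seed(31)
  for (i in 1:8) {
    s <- rnorm(12); y <- rbinom(12, 1, 0.5)
    if (length(unique(y)) < 2) next
    op2 <- youden_operating_point(s, y)
    yj <- youden_optimal_cutpoint(s[y == 1], s[y == 0])
    expect_equal(op2$youden_j, yj$youden_j)
    expect_equal(op2$balanced_accuracy, (op2$sensitivity + op2$specificity) / 2)
  }
})

test_that("cross-validated AUC is stratified, deterministic and signal-sensitive", {
  set.seed(41)
  n <- 40
  y <- rep(c(0, 1), each = n / 2)
  X_sig <- matrix(y * 3 + rnorm(n, 0, 0.5), ncol = 1)
  expect_gt(cross_validated_auc(X_sig, y, 5L, seed = 2L), 0.95)
  a1 <- cross_validated_auc(X_sig, y, 5L, seed = 7L)
  a2 <- cross_validated_auc(X_sig, y, 5L, seed = 7L)
  expect_identical(a1, a2)
  # class too small for the fold count
  expect_error(cross_validated_auc(X_sig[c(1:3, 21:38), , drop = FALSE],
                                   y[c(1:3, 21:38)], 5L, seed = 1L),
               "folds", class = "mimo_validation_error")
})

test_that("label permutation p-value is a plain exceedance proportion", {
  set.seed(43)
  n <- 30
  y <- rep(c(0, 1), each = n / 2)
  X_sig <- matrix(y * 4 + rnorm(n, 0, 0.5), ncol = 1)
  res <- label_permutation_test(X_sig, y, n_permutations = 60L, cv_folds = 3L, seed = 5L)
  expect_equal(res$permutation_p, mean(res$null_aucs >= res$observed_cv_auc))
  expect_lte(res$permutation_p, 0.05)  # strong planted signal
  expect_gte(res$permutation_p, 0)    # plain proportion: zero attainable
  expect_length(res$null_aucs, 60L)
  # deterministic given the seed
  res2 <- label_permutation_test(X_sig, y, n_permutations = 10L, cv_folds = 3L, seed = 5L)
  res3 <- label_permutation_test(X_sig, y, n_permutations = 10L, cv_folds = 3L, seed = 5L)
  expect_identical(res2$null_aucs, res3$null_aucs)
})

test_that("Fisher's exact test matches conditional enumeration on 2x2 tables", {
  expect_equal(fisher_exact(matrix(c(1, 1, 1, 1), 2, 2)), 1)
  expect_equal(fisher_exact(matrix(c(3, 0, 0, 3), 2, 2)), 0.1)
  set.seed(47)
  for (i in 1:12) {
    tab <- matrix(sample(0:6, 4, replace = TRUE), 2, 2)
    if (sum(tab) == 0 || any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    expect_equal(fisher_exact(tab), enum_fisher_2x2(tab), tolerance = 1e-9,
                 label = paste(tab, collapse = ","))
  }
  # k x 2 tables run through the exact network algorithm
  expect_lt(fisher_exact(matrix(c(9, 0, 1, 8, 4, 4), 3, 2, byrow = TRUE)), 0.05)
  expect_error(fisher_exact(matrix(0, 2, 2)), class = "mimo_validation_error")
  expect_error(fisher_exact(matrix(1, 2, 3)), class = "mimo_validation_error")
})

test_that("seropositivity rates follow POS/(POS+NEG+B)", {
  counts <- data.frame(group = c("CPSNP", "nonCPSNP", "CTRL", "EMPTY"),
                       POS = c(13, 6, 2, 0), NEG = c(12, 23, 4, 0), B = c(2, 1, 0, 0))
  rates <- seropositivity_rates(counts)
  expect_equal(unname(rates[c("nonCPSNP", "CTRL")]), c(20.0, 33.3))
  expect_equal(unname(rates["CPSNP"]), round(100 * 13 / 27, 1))
  expect_true(is.na(rates["EMPTY"]))
  expect_equal(unname(seropositivity_rates(
    data.frame(group = "g", POS = 0, NEG = 9, B = 0))["g"]), 0)
})

test_that("covariate adjustment reports stability and drops degenerate covariates", {
  set.seed(53)
  n <- 60
  y <- rep(c(0, 1), each = n / 2)
  X <- cbind(f1 = y * 2 + rnorm(n), f2 = rnorm(n))
  Z <- cbind(age = rnorm(n, 60, 7), flat = rep(1, n))
  expect_warning(chk <- adjusted_model_check(X, y, Z), "zero-variance")
  expect_equal(chk$feature, c("f1", "f2"))
  expect_true(chk$sign_agrees[chk$feature == "f1"])
  expect_lt(chk$rel_change[chk$feature == "f1"], 0.25)
})
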