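#' Fit a logistic regression classifier
#'
#' Maximum-likelihood fit via `glm(binomial)`. Under complete or
#' quasi-complete separation (fitted probabilities numerically 0/1) the fit
#' is repeated with a small L2 ridge penalty on the non-intercept
#' coefficients (Newton iterations), yielding a finite reported solution;
#' a warning notes the separation.
#'
#' @param X samples x features numeric matrix.
#' @param y binary labels (0/1 or logical).
#' @param ridge L2 penalty used by the separation fallback.
#' @return list with `coefficients` (intercept first), `fitted`
#'   (probabilities), and `separation` flag.
#' @export
fit_logistic <- function(X, y, ridge = 1e-6) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (length(unique(y)) < 2L) abort_mimo("labels are single-class", "mimo_validation_error")
  if (!all(y %in% c(0, 1))) abort_mimo("labels must be binary 0/1", "mimo_validation_error")
  sep <- FALSE
  fit <- withCallingHandlers(
    stats::glm.fit(cbind(1, X), y, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1|algorithm did not converge",
                conditionMessage(w))) {
        sep <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  # glm.fit can converge silently under complete separation: diverging
  # coefficients or saturated fitted probabilities mark it
  if (!fit$converged || anyNA(fit$coefficients) ||
      max(abs(fit$coefficients)) > 15 ||
      any(fit$fitted.values < 1e-10 | fit$fitted.values > 1 - 1e-10)) {
    sep <- TRUE
  }
  if (!sep && all(is.finite(fit$coefficients))) {
    beta <- fit$coefficients
  } else {
    warning("separation detected: refitting with L2 ridge ", format(ridge))
    beta <- ridge_logistic(cbind(1, X), y, lambda = ridge)
    sep <- TRUE
  }
  eta <- drop(cbind(1, X) %*% beta)
  list(coefficients = stats::setNames(beta, c("(Intercept)", colnames(X) %||%
                                                paste0("x", seq_len(ncol(X))))),
       fitted = stats::plogis(eta), separation = sep)
}

# Newton-Raphson for L2-penalized logistic log-likelihood (intercept
# unpenalized); damped steps, capped iterations
ridge_logistic <- function(Xi, y, lambda = 1e-6, max_iter = 200L) {
  p <- ncol(Xi)
  beta <- numeric(p)
  pen <- diag(c(0, rep(2 * lambda, p - 1L)), p)
  for (it in seq_len(max_iter)) {
    eta <- drop(Xi %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    grad <- drop(crossprod(Xi, y - mu)) - drop(pen %*% beta)
    H <- crossprod(Xi * w, Xi) + pen + diag(1e-10, p)
    step <- solve(H, grad)
    # damp large steps to keep the iteration stable under near-separation
    if (max(abs(step)) > 10) step <- step * 10 / max(abs(step))
    beta <- beta + step
    if (max(abs(step)) < 1e-8) break
  }
  beta
}

predict_logistic <- function(fit, X) {
  stats::plogis(drop(cbind(1, as.matrix(X)) %*% fit$coefficients))
}

#' Area under the ROC curve
#'
#' The probability that a random positive outscores a random negative, with
#' ties counted one half (the Mann-Whitney identity, computed from
#' midranks). Invariant under strictly monotone transforms of the scores.
#'
#' @param scores numeric prediction scores.
#' @param labels binary labels.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  y <- as.numeric(labels)
  if (length(unique(y)) < 2L) abort_mimo("both classes must be present", "mimo_validation_error")
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  r <- rank(scores)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Youden-optimal operating point of a score
#'
#' Maximizes J = sensitivity + specificity - 1 over midpoint cutpoints of
#' the scores and reports the operating characteristics there, including
#' balanced accuracy = (sensitivity + specificity) / 2.
#'
#' @param scores numeric prediction scores (higher = more positive).
#' @param labels binary labels.
#' @return list with `cutpoint`, `sensitivity`, `specificity`,
#'   `balanced_accuracy`, `youden_j`.
#' @export
youden_operating_point <- function(scores, labels) {
  y <- as.numeric(labels)
  if (length(unique(y)) < 2L) abort_mimo("both classes must be present", "mimo_validation_error")
  yj <- youden_optimal_cutpoint(scores[y == 1], scores[y == 0])
  list(cutpoint = yj$cutpoint, sensitivity = yj$sensitivity,
       specificity = yj$specificity,
       balanced_accuracy = (yj$sensitivity + yj$specificity) / 2,
       youden_j = yj$youden_j)
}

# stratified fold assignment: each fold gets a near-equal share of each class
stratified_folds <- function(y, k, seed) {
  with_seed(seed, {
    fold <- integer(length(y))
    for (cls in unique(y)) {
      idx <- sample(which(y == cls))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
    fold
  })
}

#' Cross-validated AUC of the logistic panel
#'
#' Stratified k-fold cross-validation: the logistic model is fit on each
#' training split and the AUC is computed once over the pooled out-of-fold
#' predicted probabilities. Deterministic given `seed`.
#'
#' @param X samples x features matrix.
#' @param y binary labels.
#' @param cv_folds number of folds.
#' @param seed fold-assignment seed.
#' @param ridge separation fallback penalty.
#' @return cross-validated AUC.
#' @export
cross_validated_auc <- function(X, y, cv_folds = 5L, seed = 1L, ridge = 1e-6) {
  X <- as.matrix(X); y <- as.numeric(y)
  if (min(table(y)) < cv_folds)
    abort_mimo(sprintf("smallest class (%d) cannot be stratified into %d folds; use fewer folds",
                       min(table(y)), cv_folds), "mimo_validation_error")
  fold <- stratified_folds(y, cv_folds, seed)
  pred <- numeric(length(y))
  for (f in seq_len(cv_folds)) {
    tr <- fold != f
    fit <- suppressWarnings(fit_logistic(X[tr, , drop = FALSE], y[tr], ridge = ridge))
    pred[!tr] <- predict_logistic(fit, X[!tr, , drop = FALSE])
  }
  roc_auc(pred, y)
}

#' Label-permutation significance of the cross-validated AUC
#'
#' Shuffles the outcome labels `n_permutations` times, recomputes the
#' cross-validated AUC for each shuffle (folds re-stratified per permuted
#' labels), and reports `p = mean(permuted AUC >= observed AUC)` -- the plain
#' proportion, so 0 is attainable. Deterministic given `seed`.
#'
#' @param X samples x features matrix.
#' @param y binary labels.
#' @param n_permutations number of label shuffles.
#' @param cv_folds folds for every cross-validation.
#' @param seed master seed.
#' @param ridge separation fallback penalty.
#' @return list with `observed_cv_auc`, `permutation_p`, `null_aucs`.
#' @export
label_permutation_test <- function(X, y, n_permutations = 10000L, cv_folds = 5L,
                                   seed = 1L, ridge = 1e-6) {
  if (n_permutations < 1L) abort_mimo("n_permutations must be >= 1", "mimo_validation_error")
  obs <- cross_validated_auc(X, y, cv_folds, seed = derive_seed(seed, "cv_obs"), ridge = ridge)
  y <- as.numeric(y)
  null_aucs <- vapply(seq_len(n_permutations), function(i) {
    yp <- with_seed(derive_seed(seed, paste0("perm_shuffle_", i)), sample(y))
    cross_validated_auc(X, yp, cv_folds, seed = derive_seed(seed, paste0("perm_cv_", i)),
                        ridge = ridge)
  }, numeric(1))
  list(observed_cv_auc = obs,
       permutation_p = mean(null_aucs >= obs),
       null_aucs = null_aucs)
}

#' Fisher's exact test on a k x 2 contingency table
#'
#' Exact conditional test with fixed margins: the standard two-sided
#' point-probability method for 2 x 2 tables and the network enumeration
#' for k x 2.
#'
#' @param tab non-negative integer matrix with k >= 2 rows and 2 columns.
#' @return p-value.
#' @export
fisher_exact <- function(tab) {
  tab <- as.matrix(tab)
  if (sum(tab) == 0) abort_mimo("all-zero table", "mimo_validation_error")
  if (nrow(tab) < 2L || ncol(tab) != 2L)
    abort_mimo("table must be k x 2 with k >= 2", "mimo_validation_error")
  stats::fisher.test(tab)$p.value
}

#' Per-group seropositivity rates
#'
#' Percent POS of all assayed samples per group:
#' `POS / (POS + NEG + B) * 100`, reported to one decimal. An empty group
#' yields NA.
#'
#' @param counts data.frame with columns `group`, `POS`, `NEG`, `B` (one row
#'   per group; [generate_serology_table()] layout, possibly filtered to one
#'   virus).
#' @return named numeric vector of percentages by group.
#' @export
seropositivity_rates <- function(counts) {
  tot <- counts$POS + counts$NEG + counts$B
  pct <- ifelse(tot > 0, round(100 * counts$POS / tot, 1), NA_real_)
  stats::setNames(pct, counts$group)
}

#' Covariate-adjusted stability check of the panel
#'
#' Refits the logistic panel with covariate columns (e.g. age, BMI) appended
#' and reports, per feature, the coefficient in the base and adjusted fits,
#' whether the sign agrees, and the relative change. Zero-variance
#' covariates are dropped with a warning.
#'
#' @param X samples x features matrix.
#' @param y binary labels.
#' @param covariates samples x covariates numeric matrix/data.frame.
#' @param ridge separation fallback penalty.
#' @return data.frame with columns `feature`, `coef_base`, `coef_adjusted`,
#'   `sign_agrees`, `rel_change`.
#' @export
adjusted_model_check <- function(X, y, covariates, ridge = 1e-6) {
  X <- as.matrix(X)
  Z <- as.matrix(covariates)
  if (is.null(colnames(Z))) colnames(Z) <- paste0("cov", seq_len(ncol(Z)))
  keep <- apply(Z, 2, stats::var) > 0
  if (!all(keep)) {
    warning("dropping zero-variance covariate(s): ",
            paste(colnames(Z)[!keep], collapse = ", "))
    Z <- Z[, keep, drop = FALSE]
  }
  base <- suppressWarnings(fit_logistic(X, y, ridge = ridge))
  adj <- suppressWarnings(fit_logistic(cbind(X, Z), y, ridge = ridge))
  feat <- colnames(X) %||% paste0("x", seq_len(ncol(X)))
  cb <- base$coefficients[feat]
  ca <- adj$coefficients[feat]
  data.frame(feature = feat, coef_base = unname(cb), coef_adjusted = unname(ca),
             sign_agrees = unname(sign(cb) == sign(ca)),
             rel_change = unname(abs(ca - cb) / pmax(abs(cb), 1e-12)),
             stringsAsFactors = FALSE)
}

#' Fit and validate the epitope-panel classifier
#'
#' Full classifier report: maximum-likelihood logistic fit on the feature
#' panel, apparent AUC, Youden operating point (sensitivity, specificity,
#' balanced accuracy), stratified cross-validated AUC, and the
#' label-permutation significance of the cross-validated AUC.
#'
#' @param X samples x features matrix (rows named by sample).
#' @param y binary labels (1 = case).
#' @param config a [pipeline_config()] (`cv_folds`, `n_permutations`,
#'   `ridge`).
#' @param seed master seed.
#' @param n_permutations overrides `config$n_permutations` when given.
#' @return list of class `mimo_classifier_report` with fields
#'   `feature_names`, `coefficients`, `auc`, `cv_auc`, `permutation_p`,
#'   `sensitivity`, `specificity`, `balanced_accuracy`, `cutpoint`,
#'   `separation`.
#' @export
classifier_report <- function(X, y, config = pipeline_config(),
                              seed = config$rng_seed,
                              n_permutations = config$n_permutations) {
  X <- as.matrix(X)
  fit <- suppressWarnings(fit_logistic(X, y, ridge = config$ridge))
  auc <- roc_auc(fit$fitted, y)
  op <- youden_operating_point(fit$fitted, y)
  perm <- label_permutation_test(X, y, n_permutations = n_permutations,
                                 cv_folds = config$cv_folds, seed = seed,
                                 ridge = config$ridge)
  structure(list(feature_names = colnames(X),
                 coefficients = fit$coefficients,
                 auc = auc, cv_auc = perm$observed_cv_auc,
                 permutation_p = perm$permutation_p,
                 sensitivity = op$sensitivity, specificity = op$specificity,
                 balanced_accuracy = op$balanced_accuracy,
                 cutpoint = op$cutpoint, separation = fit$separation),
            class = "mimo_classifier_report")
}

#' @export
print.mimo_classifier_report <- function(x, ...) {
  cat("<mimo_classifier_report>\n")
  cat(sprintf("  features: %s\n", paste(x$feature_names, collapse = ", ")))
  cat(sprintf("  AUC %.3f | cv-AUC %.3f | permutation p %.4g\n",
              x$auc, x$cv_auc, x$permutation_p))
  cat(sprintf("  sens %.2f | spec %.2f | balanced accuracy %.3f @ cutpoint %.3f\n",
              x$sensitivity, x$specificity, x$balanced_accuracy, x$cutpoint))
  invisible(x)
}
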