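# Exact (O(n^2)) t-SNE and DBSCAN, used by embed_and_cluster(). Both are
# deliberately plain implementations of the published algorithms: affinities
# from a perplexity-calibrated Gaussian kernel (binary search on the
# precision per point), symmetrized and exaggerated early, Student-t
# low-dimensional kernel, gradient descent with momentum; DBSCAN by
# breadth-first expansion of density-reachable core points.

#' t-SNE embedding of matrix rows
#'
#' Exact t-distributed stochastic neighbor embedding (no tree
#' approximation; quadratic in the number of rows, intended for up to a few
#' thousand epitopes). Early exaggeration 12 for the first quarter of the
#' iterations, learning rate n/12 bounded to `[50, 200]`, momentum 0.5
#' switching to 0.8. Deterministic given `seed`.
#'
#' @param X numeric matrix; rows are embedded.
#' @param dims output dimensionality.
#' @param perplexity Gaussian-kernel perplexity (effective neighbor count).
#' @param max_iter gradient-descent iterations.
#' @param seed RNG seed for the initial coordinates.
#' @return matrix of embedded coordinates, `nrow(X)` x `dims`.
#' @export
tsne_embed <- function(X, dims = 2L, perplexity = 15, max_iter = 500L, seed = 1L) {
  n <- nrow(X)
  if (n - 1 < 3 * perplexity)
    abort_mimo("perplexity too large for the number of rows", "mimo_validation_error")
  D2 <- as.matrix(stats::dist(X))^2
  P <- matrix(0, n, n)
  logU <- log(perplexity)
  for (i in seq_len(n)) {
    beta <- 1; betamin <- -Inf; betamax <- Inf
    Di <- D2[i, -i]
    for (it in seq_len(50L)) {
      Pi <- exp(-Di * beta)
      sumP <- sum(Pi)
      if (sumP == 0) { Pi <- rep(1 / length(Di), length(Di)); sumP <- 1 }
      H <- log(sumP) + beta * sum(Di * Pi) / sumP
      if (abs(H - logU) < 1e-5) break
      if (H > logU) { betamin <- beta; beta <- if (is.finite(betamax)) (beta + betamax) / 2 else beta * 2 }
      else { betamax <- beta; beta <- if (is.finite(betamin)) (beta + betamin) / 2 else beta / 2 }
    }
    P[i, -i] <- Pi / sum(Pi)
  }
  P <- (P + t(P)) / (2 * n)
  P[P < 1e-12] <- 1e-12
  exag_iter <- max(50L, round(max_iter / 4))
  Pexp <- P * 12
  Y <- with_seed(seed, matrix(stats::rnorm(n * dims, sd = 1e-4), n, dims))
  G <- matrix(0, n, dims)   # momentum buffer
  gains <- matrix(1, n, dims)
  # learning rate ~ n / early-exaggeration, bounded: large fixed rates
  # oscillate on small inputs
  eta <- max(50, min(200, n / 12))
  for (iter in seq_len(max_iter)) {
    Pi <- if (iter <= exag_iter) Pexp else P
    # Student-t kernel
    sumY <- rowSums(Y^2)
    num <- 1 / (1 + outer(sumY, sumY, "+") - 2 * Y %*% t(Y))
    diag(num) <- 0
    Q <- num / sum(num)
    Q[Q < 1e-12] <- 1e-12
    L <- (Pi - Q) * num
    grad <- 4 * (diag(rowSums(L)) - L) %*% Y
    mom <- if (iter <= 250L) 0.5 else 0.8
    gains <- ifelse(sign(grad) != sign(G), gains + 0.2, gains * 0.8)
    gains[gains < 0.01] <- 0.01
    G <- mom * G - eta * gains * grad
    Y <- Y + G
    Y <- sweep(Y, 2, colMeans(Y))
  }
  dimnames(Y) <- list(rownames(X), NULL)
  Y
}

#' DBSCAN clustering
#'
#' Density-based clustering: points with at least `min_pts` neighbors within
#' radius `eps` (themselves included) are core points; clusters are the
#' connected components of density reachability; non-reachable points are
#' labelled 0 (noise).
#'
#' @param coords numeric matrix of coordinates.
#' @param eps neighborhood radius.
#' @param min_pts minimum neighborhood size (including the point) for a core
#'   point.
#' @return integer cluster labels along rows (0 = noise).
#' @export
dbscan_cluster <- function(coords, eps = 2, min_pts = 10L) {
  n <- nrow(coords)
  D <- as.matrix(stats::dist(coords))
  nb <- lapply(seq_len(n), function(i) which(D[i, ] <= eps))
  core <- vapply(nb, length, integer(1)) >= min_pts
  labels <- integer(n)   # 0 = unvisited/noise
  cl <- 0L
  for (i in seq_len(n)) {
    if (labels[i] != 0L || !core[i]) next
    cl <- cl + 1L
    labels[i] <- cl
    queue <- setdiff(nb[[i]], i)
    while (length(queue)) {
      j <- queue[1]; queue <- queue[-1]
      if (labels[j] == 0L) {
        labels[j] <- cl
        if (core[j]) queue <- c(queue, setdiff(nb[[j]], which(labels != 0L)))
      }
    }
  }
  labels
}
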