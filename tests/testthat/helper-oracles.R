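# Independent brute-force oracles used by the unit and acceptance tests.
# Each oracle is a direct enumeration or textbook formula, deliberately kept
# free of the code paths it checks.

# P(X >= k) by enumerating every C(N, K) draw from a population with n
# successes
enum_hyper_upper <- function(k, K, n, N) {
  if (K == 0L) return(as.numeric(k <= 0))
  pop <- c(rep(1L, n), rep(0L, N - n))
  draws <- utils::combn(N, K)
  cnt <- colSums(matrix(pop[draws], nrow = K))
  mean(cnt >= k)
}

# two-sided Fisher p for a 2x2 table by point-probability enumeration over
# all tables with the observed margins
enum_fisher_2x2 <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ])
  c1 <- sum(tab[, 1])
  n <- sum(tab)
  point_p <- function(a) {
    b <- r1 - a; c <- c1 - a; d <- r2 - c
    if (b < 0 || c < 0 || d < 0) return(0)
    exp(lchoose(r1, a) + lchoose(r2, c) - lchoose(n, c1))
  }
  a_obs <- tab[1, 1]
  p_obs <- point_p(a_obs)
  a_all <- max(0, c1 - r2):min(r1, c1)
  sum(vapply(a_all, point_p, numeric(1))[vapply(a_all, point_p, numeric(1)) <= p_obs * (1 + 1e-7)])
}

# two-sided exact Wilcoxon p by enumerating every group assignment
enum_wilcox <- function(x, y) {
  n1 <- length(x)
  vals <- c(x, y)
  r <- rank(vals)
  comb <- utils::combn(length(vals), n1)
  Wd <- apply(comb, 2, function(idx) sum(r[idx])) - n1 * (n1 + 1) / 2
  w <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  min(1, 2 * min(mean(Wd <= w + 1e-9), mean(Wd >= w - 1e-9)))
}

all_perms <- function(v) {
  if (length(v) == 1L) return(list(v))
  out <- list()
  for (i in seq_along(v)) for (p in all_perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
  out
}

# two-sided exact Spearman p by enumerating all rank permutations
enum_spearman <- function(x, y) {
  rx <- rank(x)
  obs <- stats::cor(rx, rank(y))
  ps <- vapply(all_perms(seq_along(x)), function(p) stats::cor(rx, p), numeric(1))
  list(rho = obs, p = mean(abs(ps) >= abs(obs) - 1e-12))
}

# AUC by explicit positive x negative pair counting, ties worth 1/2
enum_auc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg) tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# maximum Youden J by evaluating every threshold between sorted pooled
# values, both orientations
enum_youden_j <- function(g1, g2) {
  u <- sort(unique(c(g1, g2)))
  if (length(u) == 1L) return(0)
  cuts <- (u[-1] + u[-length(u)]) / 2
  best <- 0
  for (ct in cuts) {
    best <- max(best,
                mean(g1 > ct) + mean(g2 <= ct) - 1,
                mean(g1 < ct) + mean(g2 >= ct) - 1)
  }
  best
}

# exact fraction of the n_fixed! residue orderings of a motif that match a
# sequence at least once
enum_perm_match_fraction <- function(pattern, sequence) {
  chars <- strsplit(pattern, "")[[1]]
  fixed_pos <- which(chars != ".")
  res <- chars[fixed_pos]
  hits <- vapply(all_perms(seq_along(res)), function(ord) {
    p <- chars
    p[fixed_pos] <- res[ord]
    length(exact_align(paste(p, collapse = ""), sequence)) > 0L
  }, logical(1))
  mean(hits)
}
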