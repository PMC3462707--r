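# Independent brute-force oracles.  These deliberately share no code with
# the package: grid search over rotations, exhaustive subset enumeration,
# literal step-by-step transcriptions of the selection rules, and stock
# stats:: clustering.

# minimal RMSD over rigid transforms by Euler-angle grid + Nelder-Mead
# refinement (translation handled by centering)
brute_min_rmsd <- function(P, Q) {
  Pc <- sweep(P, 2, colMeans(P))
  Qc <- sweep(Q, 2, colMeans(Q))
  rot <- function(ang) {
    cz <- cos(ang[1]); sz <- sin(ang[1])
    cy <- cos(ang[2]); sy <- sin(ang[2])
    cx <- cos(ang[3]); sx <- sin(ang[3])
    Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3)
    Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3)
    Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3)
    Rz %*% Ry %*% Rx
  }
  obj <- function(ang) sqrt(mean(rowSums((Pc %*% t(rot(ang)) - Qc)^2)))
  grid <- seq(0, 2 * pi, length.out = 13)[-13]
  best <- Inf; best_ang <- c(0, 0, 0)
  for (a in grid) for (b in grid) for (c in grid) {
    v <- obj(c(a, b, c))
    if (v < best) { best <- v; best_ang <- c(a, b, c) }
  }
  stats::optim(best_ang, obj, method = "Nelder-Mead",
               control = list(reltol = 1e-12, maxit = 5000))$value
}

# exhaustive GDT oracle: max over all fit subsets of size >= 4 of the number
# of pairs under the threshold after superposing on the subset
brute_gdt_counts <- function(X, Y, thresholds) {
  n <- nrow(X)
  counts <- setNames(rep(0, length(thresholds)), thresholds)
  for (k in 4:n) {
    subsets <- utils::combn(n, k)
    for (s in seq_len(ncol(subsets))) {
      idx <- subsets[, s]
      sp <- tryCatch(kabsch(X, Y, subset = idx), error = function(e) NULL)
      if (is.null(sp)) next
      d <- sqrt(rowSums((apply_superposition(sp, X) - Y)^2))
      for (t in seq_along(thresholds))
        counts[t] <- max(counts[t], sum(d < thresholds[t]))
    }
  }
  counts
}

# literal transcription of the pool-outlier rule: similarity of a candidate
# is its mean TM to the pool (self excluded); cutoff m_pool - alpha *
# sigma_pool with alpha = 1 for high-rankers and S/S_top (clamped to [0,1])
# for low-rankers; the top ranker always stays
brute_pool_filter <- function(ids, S, tm, high) {
  top <- ids[1]
  pool <- if (sum(ids %in% high) >= 3) ids[ids %in% high] else head(ids, 3)
  sim <- sapply(ids, function(c) {
    others <- pool[pool != c]
    if (length(others) == 0) 1 else mean(tm[c, others])
  })
  pool_sim <- sim[pool]
  m <- mean(pool_sim)
  sdev <- sqrt(sum((pool_sim - m)^2) / length(pool_sim))
  keep <- character(0)
  for (c in ids) {
    a <- if (c %in% high) 1 else min(1, max(0, S[c] / S[top]))
    if (c == top || sim[c] >= m - a * sdev) keep <- c(keep, c)
  }
  keep
}

# single-linkage clusters at a cutoff via stock hclust/cutree
brute_clusters <- function(rmsd_mat, cutoff) {
  hc <- stats::hclust(stats::as.dist(rmsd_mat), method = "single")
  stats::cutree(hc, h = cutoff)
}
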