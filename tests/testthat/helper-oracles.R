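# Brute-force oracles, written independently of the package internals:
# plain loops, mean()/var(), order() and set intersection only.  They share
# the resample index generators with the implementation so that agreement
# can be exact.

# statistic values for one (re)sampled dataset ab[, idx]; untestable peptides
# and zero denominators get -Inf (rank last)
oracle_d_column <- function(ab, idx, groups, a1, a2, min_obs = 2) {
  lev <- levels(groups)
  vapply(seq_len(nrow(ab)), function(j) {
    x1 <- ab[j, idx[groups == lev[1]]]
    x2 <- ab[j, idx[groups == lev[2]]]
    x1 <- x1[is.finite(x1)]
    x2 <- x2[is.finite(x2)]
    n1 <- length(x1); n2 <- length(x2)
    if (n1 < min_obs || n2 < min_obs) return(-Inf)
    sp2 <- (sum((x1 - mean(x1))^2) + sum((x2 - mean(x2))^2)) / (n1 + n2 - 2)
    s <- sqrt(sp2 * (1 / n1 + 1 / n2))
    den <- a1 + a2 * s
    if (den > 0) abs(mean(x1) - mean(x2)) / den else -Inf
  }, numeric(1))
}

oracle_topk <- function(d_a, d_b, k) {
  top_a <- order(-d_a, seq_along(d_a))[seq_len(k)]
  top_b <- order(-d_b, seq_along(d_b))[seq_len(k)]
  length(intersect(top_a, top_b)) / k
}

# full lattice scan: every (alpha1, alpha2) combination (alpha1 = 0 with
# alpha2 = 0 is void), every k; disjoint consecutive bootstrap pairs
oracle_rots_scan <- function(m, alpha1, alpha2, kgrid, n_bootstrap, seed,
                             min_obs = 2) {
  groups <- droplevels(m$group)
  ab <- m$abundance
  boot <- bootstrap_indices(groups, 2 * n_bootstrap, seed)
  perm <- permuted_indices(groups, 2 * n_bootstrap, seed + 1)
  fam <- expand.grid(alpha1 = alpha1, alpha2 = alpha2)
  fam <- fam[!(fam$alpha1 == 0 & fam$alpha2 == 0), , drop = FALSE]
  rows <- list()
  for (f in seq_len(nrow(fam))) {
    a1 <- fam$alpha1[f]; a2 <- fam$alpha2[f]
    db <- lapply(seq_len(nrow(boot)), function(b)
      oracle_d_column(ab, boot[b, ], groups, a1, a2, min_obs))
    dp <- lapply(seq_len(nrow(perm)), function(b)
      oracle_d_column(ab, perm[b, ], groups, a1, a2, min_obs))
    for (k in kgrid) {
      ov_b <- vapply(seq_len(n_bootstrap), function(p)
        oracle_topk(db[[2 * p - 1]], db[[2 * p]], k), numeric(1))
      ov_p <- vapply(seq_len(n_bootstrap), function(p)
        oracle_topk(dp[[2 * p - 1]], dp[[2 * p]], k), numeric(1))
      s_k <- stats::sd(ov_b)
      z <- if (s_k == 0) 0 else (mean(ov_b) - mean(ov_p)) / s_k
      rows[[length(rows) + 1]] <-
        data.frame(alpha1 = a1, alpha2 = a2, k = k, R = mean(ov_b),
                   R0 = mean(ov_p), sd = s_k, Z = z)
    }
  }
  tab <- do.call(rbind, rows)
  best <- tab[tab$Z == max(tab$Z), , drop = FALSE]
  best <- best[order(best$alpha1, best$k, best$alpha2), ][1, ]
  list(table = tab, opt = best)
}

# pooled permutation-null p-values by direct counting
oracle_pooled_p <- function(m, a1, a2, n_permutation, seed, min_obs = 2) {
  groups <- droplevels(m$group)
  ab <- m$abundance
  n <- ncol(ab)
  d_obs <- oracle_d_column(ab, seq_len(n), groups, a1, a2, min_obs)
  perm <- permuted_indices(groups, n_permutation, seed)
  null <- unlist(lapply(seq_len(nrow(perm)), function(b)
    oracle_d_column(ab, perm[b, ], groups, a1, a2, min_obs)))
  null <- null[is.finite(null)]
  vapply(d_obs, function(d) {
    if (!is.finite(d)) return(NA_real_)
    (1 + sum(null >= d)) / (1 + length(null))
  }, numeric(1))
}
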