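#' Search grid for the reproducibility optimization
#'
#' The peptide statistic `d = |mean1 - mean2| / (alpha1 + alpha2 * s)` is
#' chosen by maximizing the reproducibility Z-score over a lattice of
#' `(alpha1, alpha2, k)` values, where `k` is the top-list size.  This
#' constructor holds the lattice and the resampling settings.
#'
#' With `alpha2 = 0` the statistic reduces to the absolute fold change and its
#' ranking does not depend on `alpha1`; the family is therefore represented by
#' a single fold-change member (at the smallest positive `alpha1` of the grid)
#' plus one member per `alpha1` with `alpha2 = 1`.  The degenerate lattice
#' point `alpha1 = 0, alpha2 = 0` excludes every peptide and is skipped;
#' likewise `k = 0` is void, the smallest evaluated top-list size is 1.
#'
#' @param alpha1 non-negative grid for the additive regularizer (log2 units).
#' @param alpha2 subset of `c(0, 1)`: whether the pooled standard error enters
#'   the denominator.
#' @param k top-list sizes; `NULL` selects all `k <= 100` plus ~50 log-spaced
#'   values up to the number of peptides (`full_k = TRUE` forces all of
#'   `1..F`).
#' @param n_bootstrap number of disjoint bootstrap pairs `B` (so `2B`
#'   group-preserving resamples are drawn).
#' @param n_permutation permutation rounds for the pooled peptide p-value
#'   null.
#' @param seed integer; all resampling streams are derived from it
#'   (bootstrap resamples use `seed`, profile permutations `seed + 1`, null
#'   permutations `seed + 2`).
#' @param min_obs minimum observed values per group for a peptide to be
#'   testable (at least 2; applied per resample as well).
#' @param full_k evaluate every `k` in `1..F`.
#' @return A list of class `rots_grid`.
#' @export
rots_grid <- function(alpha1 = seq(0, 5, by = 0.01), alpha2 = c(0, 1),
                      k = NULL, n_bootstrap = 500, n_permutation = 1000,
                      seed = 1, min_obs = 2, full_k = FALSE) {
  alpha1 <- sort(unique(as.numeric(alpha1)))
  if (any(alpha1 < 0)) stopf("alpha1 must be non-negative")
  alpha2 <- sort(unique(as.numeric(alpha2)))
  if (!all(alpha2 %in% c(0, 1))) stopf("alpha2 must be a subset of {0, 1}")
  if (length(alpha2) == 0L || length(alpha1) == 0L)
    stopf("empty alpha grid")
  if (!is.null(k)) {
    k <- sort(unique(as.integer(k)))
    if (any(k < 1L)) stopf("k values must be >= 1")
  }
  n_bootstrap <- as.integer(n_bootstrap)
  if (n_bootstrap < 2L) stopf("n_bootstrap must be >= 2")
  if (min_obs < 2L) stopf("min_obs must be >= 2")
  structure(list(alpha1 = alpha1, alpha2 = alpha2, k = k,
                 n_bootstrap = n_bootstrap,
                 n_permutation = as.integer(n_permutation),
                 seed = as.integer(seed), min_obs = as.integer(min_obs),
                 full_k = isTRUE(full_k)),
            class = "rots_grid")
}

# default capped k grid: dense head, log-spaced tail
default_k_grid <- function(F, full = FALSE) {
  if (full || F <= 100L) return(seq_len(F))
  tail <- unique(as.integer(round(exp(
    seq(log(101), log(F), length.out = 50)))))
  c(1:100, tail[tail > 100L & tail <= F])
}

#' Pooled standard error of a two-group mean difference
#'
#' `s = sqrt(s_p^2 * (1/n1 + 1/n2))` with `s_p^2` the pooled (equal-variance)
#' sample variance.  Returns `NA` if either group has fewer than two observed
#' values (the peptide is then untestable).
#'
#' @param x1,x2 numeric vectors of observed values (NAs dropped).
#' @return A single numeric value.
#' @examples
#' pooled_se(c(1, 2, 3), c(4, 5, 6))  # sqrt(2/3)
#' @export
pooled_se <- function(x1, x2) {
  x1 <- x1[is.finite(x1)]; x2 <- x2[is.finite(x2)]
  n1 <- length(x1); n2 <- length(x2)
  if (n1 < 2L || n2 < 2L) return(NA_real_)
  sp2 <- (sum((x1 - mean(x1))^2) + sum((x2 - mean(x2))^2)) / (n1 + n2 - 2)
  sqrt(sp2 * (1 / n1 + 1 / n2))
}

#' Member of the t-type statistic family
#'
#' `d = |mean difference| / (alpha1 + alpha2 * s)`.  With `alpha = (0, 1)` it
#' is the absolute ordinary t-statistic; with `alpha2 = 0` it ranks by fold
#' change.  A non-positive denominator yields `NA` (peptide excluded from the
#' ranking for that alpha).
#'
#' @param mean_diff_abs absolute group mean difference(s).
#' @param s pooled standard error(s), as from [pooled_se()].
#' @param alpha1 non-negative scalar.
#' @param alpha2 0 or 1.
#' @return Numeric vector of statistic values.
#' @export
d_statistic <- function(mean_diff_abs, s, alpha1, alpha2) {
  stopifnot(alpha1 >= 0, alpha2 %in% c(0, 1))
  denom <- alpha1 + alpha2 * s
  out <- mean_diff_abs / denom
  out[!is.finite(denom) | denom <= 0] <- NA_real_
  out
}

#' Group-preserving bootstrap resamples
#'
#' Each resample draws, within each group independently, `n_g` sample
#' indices with replacement, so group sizes are preserved.  Position `j` of a
#' resample keeps the group label of sample `j` and holds an index drawn from
#' that same group.
#'
#' @param groups factor (or vector) of group labels, one per sample.
#' @param B number of resamples.
#' @param seed integer seed; same seed, same indices.
#' @return Integer matrix `B x n_samples` of sample indices.
#' @export
bootstrap_indices <- function(groups, B, seed) {
  groups <- factor(groups)
  n <- length(groups)
  with_seed(seed, {
    idx <- matrix(NA_integer_, nrow = B, ncol = n)
    for (b in seq_len(B)) {
      # draw in sorted-level order so the stream (and hence the whole fit)
      # is invariant to relabeling the two groups
      for (lev in sort(levels(groups))) {
        pos <- which(groups == lev)
        idx[b, pos] <- pos[sample.int(length(pos), length(pos),
                                      replace = TRUE)]
      }
    }
    idx
  })
}

#' Uniform label permutations
#'
#' Sample labels are permuted uniformly at random over all samples; the
#' group sizes attached to the positions are preserved.
#'
#' @inheritParams bootstrap_indices
#' @return Integer matrix `B x n_samples`; row `b` holds the permutation, so
#'   the permuted dataset is `X[, idx[b, ]]` with the original position
#'   labels.
#' @export
permuted_indices <- function(groups, B, seed) {
  n <- length(groups)
  with_seed(seed,
            t(vapply(seq_len(B), function(b) sample.int(n), integer(n))))
}

#' Overlap of two top-k lists
#'
#' `|top_k(a) intersect top_k(b)| / k` for two orderings of the same peptide
#' set (most significant first).
#'
#' @param rank_a,rank_b vectors of peptide identifiers in rank order.
#' @param k top-list size, `1 <= k <= F`.
#' @return Proportion in `[0, 1]`.
#' @export
topk_overlap <- function(rank_a, rank_b, k) {
  F <- length(rank_a)
  if (length(rank_b) != F || !setequal(rank_a, rank_b))
    stopf("rank_a and rank_b must order the same peptide set")
  if (k < 1 || k > F) stopf("k must be in 1..%d", F)
  length(intersect(rank_a[seq_len(k)], rank_b[seq_len(k)])) / k
}

# Per-resample two-group summary statistics, fully vectorized over resamples.
# idx: R x n matrix of sample indices (bootstrap draws or permutations);
# position j carries the group of sample j.  Returns F x R matrices.
resample_stats <- function(ab, idx, groups, min_obs = 2L) {
  n <- ncol(ab)
  lev <- levels(groups)
  M <- (!is.na(ab)) + 0
  X0 <- ab; X0[is.na(X0)] <- 0
  X2 <- X0^2
  R <- nrow(idx)
  W1 <- vapply(seq_len(R),
               function(b) tabulate(idx[b, groups == lev[1]], nbins = n),
               numeric(n))
  W2 <- vapply(seq_len(R),
               function(b) tabulate(idx[b, groups == lev[2]], nbins = n),
               numeric(n))
  N1 <- M %*% W1; N2 <- M %*% W2
  S1 <- X0 %*% W1; S2 <- X0 %*% W2
  Q1 <- X2 %*% W1; Q2 <- X2 %*% W2
  mean1 <- S1 / N1; mean2 <- S2 / N2
  ss1 <- pmax(Q1 - S1^2 / N1, 0)
  ss2 <- pmax(Q2 - S2^2 / N2, 0)
  df <- N1 + N2 - 2
  sp2 <- (ss1 + ss2) / df
  se <- sqrt(sp2 * (1 / N1 + 1 / N2))
  testable <- N1 >= min_obs & N2 >= min_obs
  mean_diff <- mean1 - mean2
  mean_diff[!testable] <- NA_real_
  se[!testable] <- NA_real_
  list(mean_diff = mean_diff, absdiff = abs(mean_diff), se = se,
       df = df, testable = testable)
}

# the statistic family actually evaluated: fold change first (if alpha2
# includes 0 and a positive alpha1 exists to represent it), then alpha2 = 1
# members in alpha1 order
stat_family <- function(grid) {
  fam <- data.frame(alpha1 = numeric(0), alpha2 = numeric(0))
  if (0 %in% grid$alpha2) {
    pos <- grid$alpha1[grid$alpha1 > 0]
    if (length(pos))
      fam <- rbind(fam, data.frame(alpha1 = pos[1], alpha2 = 0))
  }
  if (1 %in% grid$alpha2)
    fam <- rbind(fam, data.frame(alpha1 = grid$alpha1, alpha2 = 1))
  if (nrow(fam) == 0L)
    stopf("alpha grid contains no valid statistic (only alpha1 = 0, alpha2 = 0)")
  fam
}

#' Reproducibility profile over the statistic lattice
#'
#' For every statistic in the family and every top-list size `k`:
#' `R_k`, the mean overlap of top-k peptide lists over disjoint pairs of
#' group-preserving bootstrap datasets; `R0_k`, the same over pairs of
#' label-permuted datasets; `s_k`, the standard deviation of the bootstrap
#' overlaps; and the reproducibility Z-score
#' `Z_k = (R_k - R0_k) / s_k` (defined as 0 where `s_k = 0`).
#'
#' @param m a [peptide_matrix] with exactly two groups.
#' @param grid a [rots_grid].
#' @return A list of class `repro_profile` with matrices `R`, `R0`, `sd`,
#'   `Z` (statistics x k), the statistic family (`alpha1`, `alpha2` per row)
#'   and the `k` grid.
#' @export
reproducibility_profile <- function(m, grid = rots_grid()) {
  check_two_groups(m)
  groups <- droplevels(m$group)
  F <- nrow(m$abundance)
  if (F < 2L) stopf("need at least 2 peptides")
  kgrid <- grid$k %||% default_k_grid(F, grid$full_k)
  kgrid <- kgrid[kgrid <= F]
  fam <- stat_family(grid)
  include_fc <- fam$alpha2[1] == 0
  alpha1 <- fam$alpha1[fam$alpha2 == 1]
  B2 <- 2L * grid$n_bootstrap
  boot <- bootstrap_indices(groups, B2, grid$seed)
  perm <- permuted_indices(groups, B2, grid$seed + 1L)
  sb <- resample_stats(m$abundance, boot, groups, grid$min_obs)
  sp <- resample_stats(m$abundance, perm, groups, grid$min_obs)
  prof_b <- rots_profile_cpp(sb$absdiff, sb$se, alpha1, include_fc,
                             as.integer(kgrid))
  prof_p <- rots_profile_cpp(sp$absdiff, sp$se, alpha1, include_fc,
                             as.integer(kgrid))
  Z <- (prof_b$R - prof_p$R) / prof_b$sd
  Z[prof_b$sd == 0] <- 0
  structure(list(R = prof_b$R, R0 = prof_p$R, sd = prof_b$sd, Z = Z,
                 family = fam, k = kgrid, grid = grid),
            class = "repro_profile")
}

#' @export
print.repro_profile <- function(x, ...) {
  cat(sprintf("repro_profile: %d statistics x %d top-list sizes\n",
              nrow(x$family), length(x$k)))
  i <- which(x$Z == max(x$Z), arr.ind = TRUE)[1, ]
  cat(sprintf("max Z = %.3f at alpha = (%g, %g), k = %d\n",
              max(x$Z), x$family$alpha1[i[1]], x$family$alpha2[i[1]],
              x$k[i[2]]))
  invisible(x)
}

# argmax with deterministic tie-breaks: max Z, then smaller alpha1, then
# smaller k, then smaller alpha2
select_optimum <- function(profile) {
  Z <- profile$Z
  cand <- which(Z == max(Z), arr.ind = TRUE)
  a1 <- profile$family$alpha1[cand[, 1]]
  a2 <- profile$family$alpha2[cand[, 1]]
  kk <- profile$k[cand[, 2]]
  o <- order(a1, kk, a2)[1]
  list(alpha1 = a1[o], alpha2 = a2[o], k = kk[o], z = max(Z),
       stat_row = cand[o, 1], k_col = cand[o, 2])
}

#' Fit the reproducibility-optimized test statistic
#'
#' Maximizes the reproducibility Z-score over the `(alpha1, alpha2, k)`
#' lattice (see [reproducibility_profile()]), evaluates the winning statistic
#' on the full data, and derives two-sided peptide p-values from a pooled
#' permutation null: `p_j = (1 + #\{null |d| >= |d_j|\}) / (1 + N_null)`,
#' pooling all peptides over all permutation rounds (add-one smoothing keeps
#' p > 0).  Benjamini-Hochberg FDR is attached.
#'
#' @param m a [peptide_matrix] with exactly two groups (>= 2 samples each).
#' @param grid a [rots_grid].
#' @return An object of class `rots_fit`: optimized `alpha1`, `alpha2`, `k`,
#'   `z`; per-peptide statistic `d` (non-negative), `sign` of the group mean
#'   difference (first group minus second), `mean_diff`, `p`, `fdr`,
#'   `testable`; plus the `profile` and the `grid`.
#' @export
optimize_rots <- function(m, grid = rots_grid()) {
  lev <- check_two_groups(m)
  groups <- droplevels(m$group)
  profile <- reproducibility_profile(m, grid)
  opt <- select_optimum(profile)

  n <- ncol(m$abundance)
  full <- resample_stats(m$abundance, matrix(seq_len(n), nrow = 1), groups,
                         grid$min_obs)
  if (!any(full$testable))
    stopf("no peptide has >= %d observed values in both groups", grid$min_obs)
  d <- d_statistic(full$absdiff[, 1], full$se[, 1], opt$alpha1, opt$alpha2)
  sgn <- sign(full$mean_diff[, 1])

  nullperm <- permuted_indices(groups, grid$n_permutation, grid$seed + 2L)
  ns <- resample_stats(m$abundance, nullperm, groups, grid$min_obs)
  d0 <- d_statistic(ns$absdiff, ns$se, opt$alpha1, opt$alpha2)
  pool <- sort(d0[is.finite(d0)])
  N <- length(pool)
  if (N == 0L) stopf("empty permutation null; increase n_permutation")
  p <- rep(NA_real_, length(d))
  ok <- is.finite(d)
  # count of null values >= d via # null < d
  p[ok] <- (1 + N - findInterval(d[ok], pool, left.open = TRUE)) / (1 + N)
  fdr <- rep(NA_real_, length(p))
  fdr[ok] <- bh_fdr(p[ok])
  structure(list(alpha1 = opt$alpha1, alpha2 = opt$alpha2, k = opt$k,
                 z = opt$z, d = d, sign = sgn,
                 mean_diff = full$mean_diff[, 1],
                 p = p, fdr = fdr,
                 testable = full$testable[, 1],
                 peptide_id = rownames(m$abundance),
                 protein = m$protein, groups = lev,
                 profile = profile, grid = grid),
            class = "rots_fit")
}

#' @export
print.rots_fit <- function(x, ...) {
  cat(sprintf("rots_fit: %d peptides (%d testable), groups %s vs %s\n",
              length(x$d), sum(x$testable), x$groups[1], x$groups[2]))
  cat(sprintf("optimum: alpha = (%g, %g), k = %d, Z = %.3f\n",
              x$alpha1, x$alpha2, x$k, x$z))
  cat(sprintf("peptides with FDR < 0.05: %d\n",
              sum(x$fdr < 0.05, na.rm = TRUE)))
  invisible(x)
}
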