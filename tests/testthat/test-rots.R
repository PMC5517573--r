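test_that("pooled standard error matches the closed form", {
  expect_equal(pooled_se(c(1, 2, 3), c(4, 5, 6)), sqrt(2 / 3))
  expect_equal(pooled_se(c(5, 5), c(5, 5)), 0)
  # homogeneity: scaling both groups scales s by |c|
  x1 <- c(0.3, 1.1, 2.7); x2 <- c(4.2, 3.3)
  expect_equal(pooled_se(-3 * x1, -3 * x2), 3 * pooled_se(x1, x2))
  # fewer than two observations per group: untestable
  expect_true(is.na(pooled_se(c(1), c(2, 3))))
  expect_true(is.na(pooled_se(c(1, NA), c(2, 3))))
})

test_that("the t-type family interpolates between |t| and fold change", {
  expect_equal(d_statistic(2, 1, 0, 1), 2)          # ordinary |t|
  expect_equal(d_statistic(2, 123.4, 1, 0), 2)      # fold-change ranking
  expect_equal(d_statistic(2, 1, 0.5, 1), 2 / 1.5)  # 1.3333...
  expect_true(is.na(d_statistic(2, 0, 0, 1)))       # zero denominator
  # non-increasing in alpha1 for every peptide
  ad <- c(0.5, 1, 2); s <- c(0.2, 1, 0.7)
  grid <- seq(0, 5, by = 0.25)
  d_by_a1 <- sapply(grid, function(a1) d_statistic(ad, s, a1, 1))
  expect_true(all(diff(t(d_by_a1)) <= 0))
})

test_that("bootstrap resamples preserve group sizes and are seed-stable", {
  groups <- factor(c("A", "A", "A", "B", "B", "B"))
  idx <- bootstrap_indices(groups, 1000, seed = 5)
  expect_identical(dim(idx), c(1000L, 6L))
  # within-group draws: positions 1-3 hold indices 1-3, positions 4-6 hold 4-6
  expect_true(all(idx[, 1:3] %in% 1:3) && all(idx[, 4:6] %in% 4:6))
  expect_identical(idx, bootstrap_indices(groups, 1000, seed = 5))
  # P(all three draws distinct within one group) = 3!/3^3 = 6/27
  frac <- mean(apply(idx[, 1:3], 1, function(r) length(unique(r)) == 3L))
  p0 <- 6 / 27
  expect_lt(abs(frac - p0), 3 * sqrt(p0 * (1 - p0) / 1000))
})

test_that("label permutations are uniform and size-preserving", {
  groups <- factor(c("A", "A", "B", "B"))
  idx <- permuted_indices(groups, 500, seed = 9)
  expect_true(all(apply(idx, 1, sort) == 1:4))   # true permutations
  expect_identical(idx, permuted_indices(groups, 500, seed = 9))
  # each sample lands in the first group with frequency ~ n1/n = 1/2
  frac <- vapply(1:4, function(s) mean(idx[, 1] == s | idx[, 2] == s),
                 numeric(1))
  expect_true(all(abs(frac - 0.5) < 3 * sqrt(0.25 / 500)))
})

test_that("top-k overlap counts the intersection proportion", {
  expect_equal(topk_overlap(paste0("p", 1:4), paste0("p", 1:4), 2), 1)
  expect_equal(topk_overlap(c("p1", "p2", "p3", "p4"),
                            c("p2", "p1", "p4", "p3"), 3), 2 / 3)
  expect_equal(topk_overlap(c("p1", "p2"), c("p2", "p1"), 2), 1)  # k = F
  expect_error(topk_overlap(c("p1", "p2"), c("p2", "p1"), 3), "k must be")
})

test_that("reproducibility profile matches the brute-force oracle", {
  m <- make_toy_matrix(n_protein = 10, npep = 2, fc = 1.5, noise_sd = 0.6,
                       seed = 21)
  alpha1 <- c(0, 0.5, 2)
  kgrid <- c(1L, 2L, 5L, 10L, 20L)
  B <- 20
  grid <- rots_grid(alpha1 = alpha1, k = kgrid, n_bootstrap = B,
                    n_permutation = 100, seed = 31)
  prof <- reproducibility_profile(m, grid)
  oracle <- oracle_rots_scan(m, alpha1, c(0, 1), kgrid, B, seed = 31)

  # every represented lattice point agrees: R, R0, sd, Z
  for (f in seq_len(nrow(prof$family))) {
    for (j in seq_along(prof$k)) {
      a1 <- prof$family$alpha1[f]; a2 <- prof$family$alpha2[f]
      row <- oracle$table[oracle$table$alpha1 == a1 &
                            oracle$table$alpha2 == a2 &
                            oracle$table$k == prof$k[j], ]
      expect_equal(prof$R[f, j], row$R, tolerance = 1e-12)
      expect_equal(prof$R0[f, j], row$R0, tolerance = 1e-12)
      expect_equal(prof$sd[f, j], row$sd, tolerance = 1e-10)
      expect_equal(prof$Z[f, j], row$Z, tolerance = 1e-8)
    }
  }
})

test_that("a dominant peptide gives degenerate zero-variance overlap at k = 1", {
  # one hugely separated peptide over pure-noise peptides: every informative
  # bootstrap pair ranks it first at alpha = (0, 1), so the overlap at k = 1
  # has zero spread and the Z-score is defined as 0 there
  set.seed(77)
  ab <- rbind(big = c(0, 0.01, 0.02, 10, 10.01, 10.02),
              matrix(rnorm(5 * 6, sd = 1), 5, 6,
                     dimnames = list(paste0("noise", 1:5), NULL)))
  m <- peptide_matrix(ab, protein = paste0("P", 1:6),
                      group = rep(c("A", "B"), each = 3))
  grid <- rots_grid(alpha1 = 0, alpha2 = 1, k = c(1L, 3L), n_bootstrap = 10,
                    seed = 13)
  prof <- reproducibility_profile(m, grid)
  # verify by brute force that the overlap at k = 1 is 1 in every pair
  boot <- bootstrap_indices(droplevels(m$group), 20, 13)
  ov <- vapply(seq_len(10), function(p) {
    da <- oracle_d_column(ab, boot[2 * p - 1, ], droplevels(m$group), 0, 1)
    db <- oracle_d_column(ab, boot[2 * p, ], droplevels(m$group), 0, 1)
    oracle_topk(da, db, 1)
  }, numeric(1))
  expect_true(all(ov == 1))
  expect_equal(prof$R[1, 1], 1)
  expect_equal(prof$sd[1, 1], 0)
  expect_equal(prof$Z[1, 1], 0)       # s_k = 0 rule
})

test_that("optimization agrees exactly with the brute-force lattice scan", {
  m <- make_toy_matrix(n_protein = 10, npep = 2, fc = 2, noise_sd = 0.5,
                       seed = 51)   # F = 20 peptides
  alpha1 <- c(0, 0.5, 2)
  kgrid <- c(1L, 2L, 5L, 10L, 20L)
  grid <- rots_grid(alpha1 = alpha1, k = kgrid, n_bootstrap = 20,
                    n_permutation = 200, seed = 61)
  fit <- optimize_rots(m, grid)
  oracle <- oracle_rots_scan(m, alpha1, c(0, 1), kgrid, 20, seed = 61)
  expect_equal(fit$alpha1, oracle$opt$alpha1)
  expect_equal(fit$alpha2, oracle$opt$alpha2)
  expect_equal(fit$k, oracle$opt$k)
  expect_equal(fit$z, oracle$opt$Z, tolerance = 1e-8)
})

test_that("pooled permutation p-values match direct counting and are calibrated", {
  m <- make_toy_matrix(n_protein = 8, npep = 2, fc = 1, noise_sd = 0.5,
                       seed = 71)
  m$abundance[2, 1] <- NA                       # keep a missing value in play
  grid <- rots_grid(alpha1 = c(0.2), alpha2 = 1, k = c(1L, 4L, 8L),
                    n_bootstrap = 10, n_permutation = 150, seed = 81)
  fit <- optimize_rots(m, grid)
  # the identity/swap permutations tie the observed statistic exactly, and
  # the oracle's arithmetic differs in the last ulp, so bracket the count
  # with an epsilon instead of asserting equality of tie handling
  groups <- droplevels(m$group)
  d_obs <- oracle_d_column(m$abundance, seq_len(ncol(m$abundance)), groups,
                           fit$alpha1, fit$alpha2)
  perm <- permuted_indices(groups, 150, seed = 81 + 2)
  null <- unlist(lapply(seq_len(nrow(perm)), function(b)
    oracle_d_column(m$abundance, perm[b, ], groups, fit$alpha1, fit$alpha2)))
  null <- null[is.finite(null)]
  eps <- 1e-9
  N <- length(null)
  for (j in seq_along(d_obs)) {
    if (!is.finite(d_obs[j])) { expect_true(is.na(fit$p[j])); next }
    p_hi <- (1 + sum(null >= d_obs[j] - eps)) / (1 + N)
    p_lo <- (1 + sum(null >= d_obs[j] + eps)) / (1 + N)
    expect_gte(fit$p[j], p_lo)
    expect_lte(fit$p[j], p_hi)
  }
  expect_true(all(fit$p > 0 & fit$p <= 1, na.rm = TRUE))
  # monotone non-increasing in |d|; largest |d| has the smallest p
  ok <- !is.na(fit$p)
  o <- order(-fit$d[ok])
  expect_true(all(diff(fit$p[ok][o]) >= 0))
  expect_equal(unname(fit$p[ok][which.max(fit$d[ok])]), min(fit$p[ok]))
})

test_that("the statistic is invariant to group relabeling and seed-stable", {
  m <- make_toy_matrix(n_protein = 6, npep = 3, fc = 1, seed = 91)
  grid <- test_grid(seed = 101, n_bootstrap = 20, n_permutation = 100,
                    alpha1 = c(0, 1))
  fit <- optimize_rots(m, grid)
  fit2 <- optimize_rots(m, grid)
  expect_identical(fit$d, fit2$d)               # bit-identical rerun
  expect_identical(fit$p, fit2$p)
  expect_identical(fit$profile$Z, fit2$profile$Z)

  swapped <- peptide_matrix(m$abundance, m$protein,
                            factor(m$group, levels = rev(levels(m$group))))
  fs <- optimize_rots(swapped, grid)
  expect_equal(fs$d, fit$d)                     # |mean1 - mean2| symmetric
  expect_equal(fs$mean_diff, -fit$mean_diff)
  expect_equal(fs$sign, -fit$sign)
})

test_that("fold-change rankings are alpha1-invariant and null data is calibrated", {
  m <- make_toy_matrix(n_protein = 8, npep = 2, fc = 1, seed = 111)
  groups <- droplevels(m$group)
  n <- ncol(m$abundance)
  d_a <- oracle_d_column(m$abundance, seq_len(n), groups, 0.7, 0)
  d_b <- oracle_d_column(m$abundance, seq_len(n), groups, 3.1, 0)
  expect_identical(order(-d_a), order(-d_b))

  # on null data the peptide p-value distribution is roughly uniform
  null <- make_toy_matrix(n_protein = 60, npep = 3, fc = 0, seed = 121)
  fit <- optimize_rots(null, test_grid(seed = 131, n_bootstrap = 30,
                                       n_permutation = 300))
  frac <- mean(fit$p < 0.05, na.rm = TRUE)
  se <- sqrt(0.05 * 0.95 / sum(!is.na(fit$p)))
  expect_lt(abs(frac - 0.05), 3 * se + 0.01)
})
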