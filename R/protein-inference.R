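#' Directional score of a two-sided peptide p-value
#'
#' Folds a two-sided p-value and the sign of the group mean difference into a
#' single score `u` that is Uniform(0,1) under the null: `u = p/2` for
#' up-regulation (positive difference), `u = 1 - p/2` for down-regulation,
#' and `u = 0.5` when the difference is exactly zero.  Small `u` means strong
#' up-regulation, large `u` strong down-regulation.
#'
#' @param p_two_sided two-sided p-value(s) in (0, 1].
#' @param sign sign(s) of the group mean difference (-1, 0, +1).
#' @return Numeric vector of scores in \[0, 1\].
#' @export
directional_score <- function(p_two_sided, sign) {
  if (any(p_two_sided <= 0 | p_two_sided > 1, na.rm = TRUE))
    stopf("p-values must be in (0, 1]")
  ifelse(sign > 0, p_two_sided / 2,
         ifelse(sign < 0, 1 - p_two_sided / 2, 0.5))
}

#' Significance of the median of n uniform scores
#'
#' Under the null the peptide scores of a protein are n independent
#' Uniform(0,1) draws, whose i-th order statistic follows Beta(i, n - i + 1).
#' With `i = ceiling(n / 2)` (the lower-central order statistic for even n)
#' this returns the lower-tail probability of observing a median score at
#' most `P_m`: the regularized incomplete beta function at `P_m`.
#'
#' @param P_m observed median score(s) in \[0, 1\].
#' @param n number of peptides (>= 1); recycled against `P_m`.
#' @return Lower-tail probability (vector).
#' @examples
#' beta_median_significance(0.3, 1)     # 0.3: Beta(1,1) is uniform
#' beta_median_significance(0.25, 3)    # 3x^2 - 2x^3 at 0.25 = 0.15625
#' @export
beta_median_significance <- function(P_m, n) {
  if (any(n < 1)) stopf("n must be >= 1")
  if (any(P_m < 0 | P_m > 1, na.rm = TRUE)) stopf("P_m must be in [0, 1]")
  i <- ceiling(n / 2)
  stats::pbeta(P_m, shape1 = i, shape2 = n - i + 1)
}

#' Benjamini-Hochberg false discovery rate
#'
#' Step-up adjusted p-values, monotone, capped at 1, in the original order.
#'
#' @param p numeric vector of p-values in (0, 1].
#' @return Adjusted values, same length and order.
#' @export
bh_fdr <- function(p) {
  if (length(p) == 0L) return(numeric(0))
  if (any(p <= 0 | p > 1, na.rm = TRUE)) stopf("p-values must be in (0, 1]")
  stats::p.adjust(p, method = "BH")
}

# beta order-statistic aggregation of peptide evidence shared by
# ropeca()/peca(): two-sided protein p from the median directional score
aggregate_to_protein <- function(protein, p, sgn, mean_diff, testable) {
  keep <- testable & !is.na(p)
  all_prot <- unique(unname(protein))
  dropped <- setdiff(all_prot, unique(unname(protein[keep])))
  if (length(dropped))
    warning(sprintf("%d protein(s) without testable peptides omitted",
                    length(dropped)), call. = FALSE)
  protein <- protein[keep]
  u <- directional_score(p[keep], sgn[keep])
  md <- mean_diff[keep]
  key <- factor(protein, levels = unique(unname(protein)))
  n <- as.integer(table(key)[levels(key)])
  i <- ceiling(n / 2)
  ord <- order(key, u)
  u_sorted <- u[ord]
  first <- c(0L, cumsum(n)[-length(n)])
  P_m <- u_sorted[first + i]
  Fbeta <- stats::pbeta(P_m, i, n - i + 1)
  p_protein <- 2 * pmin(Fbeta, 1 - Fbeta)
  p_protein <- pmin(pmax(p_protein, .Machine$double.xmin), 1)
  slr <- as.numeric(tapply(md, key, stats::median))
  data.frame(protein_id = levels(key), n_peptides = n, slr = slr,
             P_m = P_m, p = p_protein, fdr = bh_fdr(p_protein),
             stringsAsFactors = FALSE)
}

new_protein_de <- function(table, method, fit = NULL, groups = NULL,
                           call = NULL) {
  rownames(table) <- NULL
  structure(list(table = table, method = method, fit = fit,
                 groups = groups, call = call),
            class = "protein_de")
}

#' Reproducibility-optimized peptide change averaging
#'
#' The main fitting function.  Peptide-level two-group statistics are
#' optimized with [optimize_rots()]; per protein, the two-sided peptide
#' p-values and their signs are folded into directional scores, the
#' `ceiling(n/2)`-th smallest score is the protein's median score `P_m`, and
#' the protein p-value is the two-sided tail of the Beta(i, n - i + 1)
#' distribution of that order statistic:
#' `p = 2 * min(F(P_m), 1 - F(P_m))`.  The signal log2-ratio (`slr`) is the
#' median of the peptide mean differences.  FDR is Benjamini-Hochberg across
#' proteins.
#'
#' @param m a [peptide_matrix] of normalized log2 abundances with exactly two
#'   groups.
#' @param grid a [rots_grid] controlling the statistic lattice and the
#'   resampling.
#' @return An object of class `protein_de` whose `$table` has one row per
#'   protein with columns `protein_id`, `n_peptides` (testable peptides),
#'   `slr`, `P_m`, `p`, `fdr`; `$fit` holds the underlying `rots_fit`.
#' @seealso [peca()] for the non-optimized variant, [protein_ttest()] for the
#'   roll-up baseline.
#' @export
ropeca <- function(m, grid = rots_grid()) {
  fit <- optimize_rots(m, grid)
  tab <- aggregate_to_protein(fit$protein, fit$p, fit$sign, fit$mean_diff,
                              fit$testable)
  new_protein_de(tab, "ropeca", fit = fit, groups = fit$groups,
                 call = match.call())
}

# per-peptide ordinary equal-variance t-test on log2 values
peptide_ttest_stats <- function(m, min_obs = 2L) {
  lev <- check_two_groups(m)
  groups <- droplevels(m$group)
  n <- ncol(m$abundance)
  full <- resample_stats(m$abundance, matrix(seq_len(n), nrow = 1), groups,
                         min_obs)
  mean_diff <- full$mean_diff[, 1]
  se <- full$se[, 1]
  df <- full$df[, 1]
  t <- mean_diff / se
  p <- 2 * stats::pt(-abs(t), df)
  zero_se <- full$testable[, 1] & is.finite(mean_diff) & se == 0
  p[zero_se & mean_diff == 0] <- 1
  p[zero_se & mean_diff != 0] <- .Machine$double.xmin
  list(p = p, sign = sign(mean_diff), mean_diff = mean_diff,
       testable = full$testable[, 1], groups = lev, t = t, df = df)
}

#' Peptide change averaging with ordinary t-tests
#'
#' Identical protein-level aggregation to [ropeca()], but the peptide
#' p-values come from the ordinary two-sample equal-variance t-test
#' (two-sided, t distribution with `n1 + n2 - 2` degrees of freedom) instead
#' of the reproducibility-optimized statistic.  Recommended over [ropeca()]
#' for data with many missing values and few samples, where the bootstrap
#' becomes unstable.
#'
#' @inheritParams ropeca
#' @param min_obs minimum observed values per group for a peptide to be
#'   testable.
#' @return A `protein_de` object (see [ropeca()]).
#' @export
peca <- function(m, min_obs = 2L) {
  st <- peptide_ttest_stats(m, min_obs)
  tab <- aggregate_to_protein(m$protein, st$p, st$sign, st$mean_diff,
                              st$testable)
  new_protein_de(tab, "peca", fit = st[c("p", "sign", "mean_diff",
                                         "testable", "t", "df")],
                 groups = st$groups, call = match.call())
}

#' @export
print.protein_de <- function(x, ...) {
  cat(sprintf("protein_de fit (%s): %d proteins, groups %s vs %s\n",
              x$method, nrow(x$table),
              x$groups[1] %||% "?", x$groups[2] %||% "?"))
  cat(sprintf("proteins with FDR < 0.05: %d\n", sum(x$table$fdr < 0.05)))
  top <- x$table[order(x$table$p), , drop = FALSE]
  print(utils::head(top, 5), row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
summary.protein_de <- function(object, fdr = c(0.01, 0.05, 0.1), ...) {
  tab <- object$table
  out <- list(method = object$method, n_proteins = nrow(tab),
              groups = object$groups,
              detections = vapply(fdr, function(t) sum(tab$fdr <= t),
                                  integer(1)),
              fdr_thresholds = fdr,
              alpha = if (inherits(object$fit, "rots_fit"))
                c(object$fit$alpha1, object$fit$alpha2),
              k = if (inherits(object$fit, "rots_fit")) object$fit$k,
              z = if (inherits(object$fit, "rots_fit")) object$fit$z)
  class(out) <- "summary.protein_de"
  out
}

#' @export
print.summary.protein_de <- function(x, ...) {
  cat(sprintf("Differential protein expression (%s), %d proteins\n",
              x$method, x$n_proteins))
  if (!is.null(x$alpha))
    cat(sprintf("optimized statistic: alpha = (%g, %g), k = %d, Z = %.3f\n",
                x$alpha[1], x$alpha[2], x$k, x$z))
  for (j in seq_along(x$fdr_thresholds))
    cat(sprintf("  FDR <= %.2f: %d proteins\n", x$fdr_thresholds[j],
                x$detections[j]))
  invisible(x)
}

#' @export
coef.protein_de <- function(object, ...) {
  stats::setNames(object$table$slr, object$table$protein_id)
}

#' @export
as.data.frame.protein_de <- function(x, ...) x$table

#' @export
plot.protein_de <- function(x, fdr = 0.05, ...) {
  tab <- x$table
  sig <- tab$fdr <= fdr
  plot(tab$slr, -log10(tab$p),
       xlab = "signal log2-ratio", ylab = "-log10 p",
       main = sprintf("%s: %d of %d proteins at FDR <= %g",
                      x$method, sum(sig), nrow(tab), fdr),
       pch = 20, col = ifelse(sig, "firebrick", "grey50"), ...)
  abline(v = 0, lty = 3)
  invisible(x)
}

#' Write a protein result table to TSV
#'
#' Columns `protein_id`, `n_peptides`, `slr`, `p`, `fdr`, one row per
#' protein, sorted by p-value.
#'
#' @param x a `protein_de` fit or its `$table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_protein_results <- function(x, path) {
  tab <- if (inherits(x, "protein_de")) x$table else x
  tab <- tab[order(tab$p), intersect(c("protein_id", "n_peptides", "slr",
                                       "p", "fdr"), colnames(tab))]
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a generic protein result table
#'
#' Accepts the package's own output as well as external comparator tables
#' with at least `protein_id` and `p` (optionally `fdr`, `slr`,
#' `n_peptides`).  Missing `fdr` is recomputed with [bh_fdr()].
#'
#' @param path TSV path.
#' @return A data.frame.
#' @export
read_protein_results <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                           stringsAsFactors = FALSE, check.names = FALSE)
  if (!all(c("protein_id", "p") %in% colnames(tab)))
    stopf("protein results need columns 'protein_id' and 'p'")
  if (is.null(tab$fdr)) tab$fdr <- bh_fdr(tab$p)
  tab
}
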