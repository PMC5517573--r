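#' Protein-level equal-variance t-test baseline
#'
#' Two-sided two-group t-test with equal variances on log2 protein
#' abundances (typically a [rollup_sum()] of normalized peptides), with
#' Benjamini-Hochberg FDR.  Proteins with fewer than `min_obs` observed
#' values in either group are omitted.  `slr` is the group mean difference.
#'
#' @param pm a `protein_matrix` (or any [peptide_matrix] whose rows are
#'   proteins) with exactly two groups.
#' @param min_obs minimum observed values per group.
#' @return A `protein_de` object (method `"ttest"`).
#' @export
protein_ttest <- function(pm, min_obs = 2L) {
  st <- peptide_ttest_stats(pm, min_obs)
  keep <- st$testable & !is.na(st$p)
  if (!any(keep)) stopf("no testable proteins")
  npep <- attr(pm, "n_peptides") %||% rep(1L, nrow(pm$abundance))
  tab <- data.frame(protein_id = rownames(pm$abundance)[keep],
                    n_peptides = npep[keep],
                    slr = st$mean_diff[keep],
                    p = pmin(pmax(st$p[keep], .Machine$double.xmin), 1),
                    stringsAsFactors = FALSE)
  tab$fdr <- bh_fdr(tab$p)
  new_protein_de(tab, "ttest", fit = st[c("t", "df")], groups = st$groups,
                 call = match.call())
}

#' Protein-level reproducibility-optimized test baseline
#'
#' Applies the reproducibility-optimized statistic of [optimize_rots()]
#' directly to a protein-level matrix (proteins take the role of peptides),
#' without any peptide aggregation.  This is the protein-level counterpart
#' used to contrast direct optimization with peptide-level averaging.
#'
#' @param pm a `protein_matrix` with exactly two groups.
#' @param grid a [rots_grid].
#' @return A `protein_de` object (method `"rots"`).
#' @export
protein_rots <- function(pm, grid = rots_grid()) {
  fit <- optimize_rots(pm, grid)
  keep <- fit$testable & !is.na(fit$p)
  npep <- attr(pm, "n_peptides") %||% rep(1L, nrow(pm$abundance))
  tab <- data.frame(protein_id = fit$peptide_id[keep],
                    n_peptides = npep[keep],
                    slr = fit$mean_diff[keep],
                    p = fit$p[keep],
                    fdr = bh_fdr(fit$p[keep]),
                    stringsAsFactors = FALSE)
  new_protein_de(tab, "rots", fit = fit, groups = fit$groups,
                 call = match.call())
}
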