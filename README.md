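# ropeca

Differential protein expression for label-free proteomics — in particular
data-independent acquisition (DIA/SWATH) data with consistent peptide-level
measurements — by **reproducibility-optimized peptide change averaging**.

Most workflows either roll peptide intensities up to protein level before
testing (losing the per-peptide evidence) or fit peptide-level models whose
error control degrades with small samples. `ropeca` instead:

1. **Optimizes the peptide-level test statistic for reproducibility.**
   For each peptide, a statistic from the t-type family

   d_α = |x̄₁ − x̄₂| / (α₁ + α₂·s),

   with s the pooled standard error, is chosen by maximizing the
   reproducibility Z-score

   Z_k(d_α) = (R_k(d_α) − R⁰_k(d_α)) / s_k(d_α)

   over a lattice α₁ ∈ {0, 0.01, …, 5}, α₂ ∈ {0, 1}, k ∈ {1, …, F}, where
   R_k is the mean overlap of the k top-ranked peptides across pairs of
   group-preserving bootstrap datasets, R⁰_k the same in label-permuted
   data, and s_k the bootstrap standard deviation of the overlap.  Two-sided
   peptide p-values come from a pooled permutation null.

2. **Aggregates peptide evidence to proteins through order statistics.**
   Each peptide's two-sided p-value and direction of change are folded into
   a directional score u (uniform under the null); for a protein with n
   testable peptides the central order statistic u₍ᵢ₎, i = ⌈n/2⌉, follows
   Beta(i, n − i + 1) under the null, so the protein-level significance is
   the two-sided tail of that beta distribution at the observed median
   score P_m.  FDR is controlled by Benjamini–Hochberg.

The package also ships the comparison baselines (protein-level equal-variance
t-test on summed intensities; the reproducibility-optimized statistic applied
directly at protein level), PECA (the same aggregation with plain t-tests,
recommended for sparse shotgun data), synthetic spike-in and hybrid-proteome
benchmark generators with ground truth, and evaluation utilities (merged ROC
curves, normalized partial AUC above specificity 0.9, bootstrap pAUC tests,
TP/FP-vs-FDR curves, subset-overlap and mock-split analyses).

## Worked example

Simulate a hybrid-proteome-like benchmark (200 proteins, 35% truly
differential with log2 fold changes +2 and −1, five peptides per protein on
average, three replicates per group), normalize, fit, and benchmark:

```r
library(ropeca)

st  <- simulate_hybrid(sim_config(n_background = 188, n_spike = 12,
                                  peptides_per_protein = 5,
                                  peptide_noise_sd = 0.4, seed = 1),
                       fraction_differential = 0.35)
m   <- median_normalize(st$matrix)
fit <- ropeca(m, rots_grid(alpha1 = seq(0, 5, 0.1), n_bootstrap = 100,
                           n_permutation = 500, seed = 2))
fit
#> protein_de fit (ropeca): 200 proteins, groups A vs B
#> proteins with FDR < 0.05: 74
#>  protein_id n_peptides    slr    P_m         p       fdr
#>    PROT0139         10 -1.944 0.9966 5.944e-13 1.189e-10
#>    PROT0162          8 -1.925 0.9954 2.265e-10 2.265e-08
#>    PROT0135          8 -1.780 0.9948 4.252e-10 2.834e-08
#>    PROT0145          6 -1.976 0.9970 2.577e-09 1.288e-07
#>    PROT0164          6 -1.914 0.9957 1.004e-08 4.016e-07

summary(fit)
#> Differential protein expression (ropeca), 200 proteins
#> optimized statistic: alpha = (0.6, 1), k = 272, Z = 9.996
#>   FDR <= 0.01: 68 proteins
#>   FDR <= 0.05: 74 proteins
#>   FDR <= 0.10: 81 proteins

merged_roc(fit, st$is_differential)
#> eval_roc: 70 positives, 130 negatives, 201 ROC points
#> normalized pAUC (specificity > 0.9): 0.9857
```

Reading the output: `slr` is the signal log2-ratio (median peptide log2
difference, group A minus group B — the truly up-shifted proteins in group B
therefore show slr ≈ −2), `P_m` the median directional score (near 1 =
strong down in A relative to B, near 0 = strong up), `p`/`fdr` the
beta-aggregated protein significance.  The optimizer settled on α = (0.6, 1),
a statistic between fold change and the ordinary t-statistic.  On the same
data the protein-level t-test baseline reaches a pAUC of 0.96, below the
0.986 above — the peptide-level averaging is what buys the extra ranking
power at high specificity.

The same pipeline is scriptable from a shell:

```sh
cli=$(Rscript -e 'cat(system.file("cli", "ropeca.R", package = "ropeca"))')
Rscript "$cli" simulate --scenario inst/extdata/scenario-hybrid.yaml --out-dir demo
Rscript "$cli" run --peptides demo/peptides.tsv --design demo/design.tsv \
    --method ropeca --out demo/results.tsv --seed 1
Rscript "$cli" evaluate --results demo/results.tsv --truth demo/truth.tsv \
    --out demo/report.tsv
```

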