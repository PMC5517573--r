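---
title: "Reproducibility-optimized peptide change averaging: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reproducibility-optimized peptide change averaging: model and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ropeca)
```

## The problem

In label-free quantitative proteomics, differential expression is ultimately
a statement about proteins, but the measurements are peptide intensities.
DIA/SWATH acquisition yields consistent peptide-level quantifications across
samples, which makes it attractive to test at the peptide level and only then
combine the evidence per protein — rather than summing intensities first and
discarding the within-protein replication.  With the tiny group sizes typical
of proteomics (often three replicates), however, the choice of peptide-level
test statistic matters a great deal, and no single fixed statistic is best
across data sets.

`ropeca` addresses both issues: it *selects* the peptide statistic
data-adaptively by maximizing the reproducibility of the resulting rankings,
and it *aggregates* peptide significance to proteins through an
order-statistic argument.

## Peptide-level model

For peptide $j$ with observed log2 abundances in two groups, the statistic
family is

$$d_\alpha(j) = \frac{|\bar x_1 - \bar x_2|}{\alpha_1 + \alpha_2\, s_j},$$

where $s_j$ is the pooled standard error,
$s_j = \sqrt{s_p^2 (1/n_1 + 1/n_2)}$ with the equal-variance pooled sample
variance $s_p^2$.  The family interpolates between the absolute fold change
($\alpha = (\cdot, 0)$) and the ordinary absolute t-statistic
($\alpha = (0, 1)$); intermediate $\alpha_1 > 0$ act like the variance
regularizers familiar from moderated statistics, damping the small-variance
artifacts of tiny samples.

The parameters are chosen by maximizing the reproducibility Z-score

$$Z_k(d_\alpha) = \frac{R_k(d_\alpha) - R^0_k(d_\alpha)}{s_k(d_\alpha)},$$

where $R_k$ is the mean proportion of shared peptides among the top $k$
ranked by $d_\alpha$ in pairs of group-preserving bootstrap datasets, $R^0_k$
is the same quantity in datasets whose sample labels were permuted, and
$s_k$ is the standard deviation of the bootstrap overlaps.  The search runs
over the lattice $\alpha_1 \in \{0, 0.01, \ldots, 5\}$ (step configurable),
$\alpha_2 \in \{0, 1\}$ and top-list sizes $k$.

Implementation notes on the lattice:

* For $\alpha_2 = 0$ the ranking is identical for every $\alpha_1 > 0$, so
  that whole half of the lattice is represented by a single fold-change
  member; $(\alpha_1, \alpha_2) = (0, 0)$ excludes every peptide and is
  void, as is $k = 0$.
* Overlap at every $k$ is computed in one pass per bootstrap pair via
  $|{\rm top}_k(a) \cap {\rm top}_k(b)| = \#\{j : \max({\rm rank}_a(j),
  {\rm rank}_b(j)) \le k\}$, which makes the full $k$ sweep linear in the
  number of peptides.
* Ties in $Z$ are broken toward smaller $\alpha_1$, then smaller $k$, then
  smaller $\alpha_2$, deterministically; ties in $d$ rank by input order.
* $s_k = 0$ (reachable on small or degenerate data) defines $Z_k = 0$ and
  the point is effectively excluded from the maximization.

**Bootstrap pairing.**  "Pairs of bootstrap datasets" could mean all
$\binom{B}{2}$ pairs or disjoint pairs; we draw $2B$ resamples and pair them
disjointly.  Disjoint pairs give independent overlap observations, an
unbiased standard deviation $s_k$, and linear cost.

**Peptide p-values.**  The optimized statistic has no closed-form null, so
two-sided p-values come from a pooled permutation null: all peptides' $|d|$
values over all permutation rounds form one pool, and
$p_j = (1 + \#\{|d^0| \ge |d_j|\})/(1 + N_{\rm null})$.  Pooling is valid
because peptides are exchangeable under the global null; the add-one
smoothing guarantees $p > 0$.  Peptides with fewer than `min_obs` (default
2) observed values in a group are untestable: they rank last inside
resamples and are excluded (with a warning at protein level) from the final
results.

**Randomness.**  One integer seed drives everything; the stream order is
fixed (bootstrap resamples at `seed`, profile permutations at `seed + 1`,
null permutations at `seed + 2`), the bootstrap draws iterate groups in
sorted label order so a fit is invariant to relabeling the two groups, and
no function disturbs the caller's RNG state.

## Protein-level aggregation

Each peptide's two-sided p-value and sign fold into a directional score
$u = p/2$ (up), $1 - p/2$ (down), $0.5$ (no change), which is Uniform(0,1)
under the null.  For a protein with $n$ testable peptides the central order
statistic $u_{(i)}$, $i = \lceil n/2 \rceil$, follows
${\rm Beta}(i,\, n - i + 1)$ under the null; the protein's median score
$P_m = u_{(i)}$ is therefore referred to that beta distribution, and the
reported protein p-value is the two-sided tail
$p = 2\min\{F(P_m),\, 1 - F(P_m)\}$.  The signal log2-ratio (`slr`) is the
median of the peptide mean differences (first group minus second).
Benjamini–Hochberg FDR is applied across proteins.

Two deliberate choices here were genuinely open:

* **Even $n$.**  The beta argument needs an actual order statistic, so for
  even $n$ we use the lower-central one, $i = n/2$ (from
  $i = \lceil n/2 \rceil$).  A consequence worth knowing: relabeling the two
  groups maps $u \mapsto 1 - u$, whose $i$-th smallest value is the
  *upper*-central order statistic of the original scores, so protein
  p-values of even-$n$ proteins are not exactly invariant under relabeling
  (odd-$n$ proteins are).  Under the null the p-value remains exactly
  uniform either way, by the probability integral transform.
* **Two-sidedness.**  The beta CDF is a one-tail probability; doubling the
  smaller tail gives a two-sided protein p-value with detections in both
  directions, consistent with reporting signed `slr`.

`peca()` is the same aggregation with ordinary equal-variance t-test
p-values per peptide.  It needs no resampling, which keeps it usable on
sparse shotgun data where heavy missingness would destabilize the bootstrap
overlap estimates; with the lattice pinned to $\alpha = (0, 1)$ the
optimized fit ranks peptides identically to `peca()`.

## Baselines

`protein_ttest()` is the classical roll-up baseline: peptide intensities are
summed per protein on the intensity scale (`rollup_sum()`: unlog, sum over
observed values, relog; a protein is missing only where all its peptides
are) and a two-sided equal-variance t-test is applied to the log2 protein
values.  `protein_rots()` applies the reproducibility-optimized statistic
directly at protein level, isolating the contribution of peptide-level
averaging from that of reproducibility optimization.

## Normalization and input conventions

Everything internal is log2; raw intensities can be log2-transformed on
read.  `median_normalize()` shifts each sample so all column medians (over
observed values) equal the global median of the pre-normalization column
medians — equalization rather than subtraction-to-zero, preserving the
intensity magnitude.  Missing values stay missing; nothing is imputed.
Duplicate quantifications of one peptide are summed on the intensity scale
(`sum_duplicate_peptides()`).

## The synthetic benchmark generators

The generators emulate the two standard benchmark designs with known ground
truth:

* `simulate_spikein()`: a constant background plus a small set of spiked
  proteins shifted in the second group.  The default fold-change ladder uses
  three "mixes" with adjacent-step ratios of about 1.1, 0.63 and 4
  (log2: 0.1375, −0.67, 2), i.e. subtle, moderate-down and strong-up
  spikes over an unchanged background.
* `simulate_hybrid()`: a stated fraction (default 35%) of all proteins is
  differential, split between an up subset (+2 in log2, a 4-fold increase)
  and a down subset (−1, a 2-fold decrease) — the structure of a
  two-proteome mixture where one organism's share rises from 5% to 20% and
  another's falls from 30% to 15% over a constant 65% background.  The
  shipped composition table (`hybrid_composition()`) encodes exactly that
  design, and `differential_fraction()` recovers the 35%.

The signal model per peptide is `protein baseline + peptide offset + group
effect + noise`, all Gaussian on the log2 scale: baseline N(20, 2) (typical
log2 intensity scale), per-peptide offset N(0, 1) (ionization-efficiency
spread), residual noise N(0, 0.3) by default (0.4 in the harder hybrid
scenario) — values in the range reported for label-free DIA replicates.
Peptide counts per protein are 1 + Poisson(mean − 1), so "4 peptides per
protein" means a mean of 4 with a minimum of one.  Missingness is MCAR by
default, with an optional abundance-driven logistic mode for DDA-like data.
Group sizes default to 3 vs 3, the prototypical benchmark layout.

What the generator deliberately does *not* reproduce: within-protein
correlation of peptide statistics (peptide offsets cancel in the group
difference, so peptide tests are independent given the truth), interference
and shared peptides, retention-time or batch structure, heavy-tailed noise.
Passing tests on these simulations therefore demonstrates correctness and
calibration of the statistics under the stated model, not performance on
real instrument data.

## Calibration under the idealized null

A consequence of independent peptides worth spelling out: on the pure-null
generator the protein p-values are *exactly* uniform (verified by KS tests
and tail counts in the test suite), and by the Simes equality the
probability that Benjamini–Hochberg makes at least one (necessarily false)
detection at level 0.05 under the global null is then exactly 0.05.  The
mean realized false-discovery proportion across null replicates therefore
sits *on* the nominal bound rather than safely below it; finite replicate
averages fluctuate around 0.05.  The strong conservatism reported for
mock comparisons on real data (empirical FDR near zero) stems from
correlated peptides and proteins in real matrices, which this idealized
generator intentionally omits.

## Evaluation utilities

`merged_roc()` pools (p-value, truth) pairs across comparisons and sweeps
the threshold, grouping tied p-values into single ROC steps.  `pauc()`
integrates sensitivity over specificity in [0.9, 1] by trapezoid in sweep
order (vertical segments contribute nothing) and divides by the range width
0.1, so a perfect method scores 1.0 and an uninformative one 0.05.  Reported
pAUC values in the 0.84–0.95 range are consistent with this normalization
and not with the raw area over a width-0.1 strip, which is why it is the
default; a McClish-corrected variant (`method = "mcclish"`, diagonal mapped
to 0.5) is available behind a flag.  `pauc_bootstrap_test()` resamples
proteins stratified by truth class and counts resamples where one method's
pAUC falls below the other's, ties counting half.  `tp_fp_curves()`,
`detection_overlap()` and `filter_detections()` implement the FDR-sweep
counts, the subset-recovery proportion (denominator: the full-data
detections) and the replicated-detection filter (detected in both runs, more
than one peptide, consistent fold-change direction).

## Problem sizes and numerical settings used in the shipped checks

The package defaults are a 0.01-step $\alpha_1$ lattice, $B = 500$ bootstrap
pairs and 1000 permutation rounds.  The test suite and the acceptance script
run the same code on coarsened settings — a 0.1-step lattice, $B$ = 50–100,
400–500 permutation rounds, simulations of 200–500 proteins — chosen so the
whole suite completes in minutes on one CPU while leaving every qualitative
conclusion unchanged (the null-calibration and method-ordering results are
insensitive to the lattice step, and the capped default $k$ grid — all
$k \le 100$ plus ~50 log-spaced values — tracks the full grid because $Z$
varies slowly in $k$).

## Known limitations

* Two-group designs only; no paired or multi-group support.
* Equal-variance pooling per peptide; no moderation across peptides beyond
  the $\alpha_1$ regularizer.
* The bootstrap overlap machinery needs enough complete peptides; with very
  sparse data `peca()` is the recommended fallback.
* Fragment-level evidence is not used; aggregation starts at peptides.
* Permutation granularity at 3 vs 3 is coarse (20 label assignments);
  pooling across peptides restores resolution but makes peptide p-values
  weakly dependent through the shared null pool.
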