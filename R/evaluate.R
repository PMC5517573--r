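# normalize the (results, truth) inputs of the evaluation ops to a pooled
# data.frame of (p, truth)
pool_results <- function(results, truth) {
  if (inherits(results, "protein_de")) results <- list(results)
  if (is.data.frame(results)) results <- list(results)
  if (!is.list(truth) || is.data.frame(truth)) truth <- list(truth)
  if (length(truth) == 1L && length(results) > 1L)
    truth <- rep(truth, length(results))
  if (length(truth) != length(results))
    stopf("results and truth lengths differ")
  pooled <- mapply(function(r, tr) {
    if (inherits(r, "protein_de")) r <- r$table
    flag <- if (is.data.frame(tr))
      stats::setNames(as.logical(tr$is_differential), tr$protein_id)
    else stats::setNames(as.logical(tr), names(tr))
    if (is.null(names(flag)))
      stopf("truth must be named by protein_id")
    miss <- setdiff(r$protein_id, names(flag))
    if (length(miss))
      stopf("truth missing for %d protein(s), e.g. %s", length(miss), miss[1])
    data.frame(p = r$p, truth = flag[r$protein_id])
  }, results, truth, SIMPLIFY = FALSE)
  do.call(rbind, pooled)
}

#' Merged ROC curve over one or several comparisons
#'
#' Pools `(p-value, truth)` pairs across comparisons and computes a single
#' ROC curve by sweeping the p-value threshold; equal p-values form single
#' ROC steps.
#'
#' @param results a `protein_de` fit, a data.frame with `protein_id` and `p`,
#'   or a list of either (one per comparison).
#' @param truth per-comparison ground truth: a logical vector named by
#'   protein, or a data.frame with `protein_id` and `is_differential`, or a
#'   list of either (a single truth is recycled).
#' @return An object of class `eval_roc`: `$roc` with columns `specificity`,
#'   `sensitivity` (threshold sweep from strict to lax), `$pauc` (normalized
#'   partial AUC above specificity 0.9), `$n_pos`, `$n_neg`.
#' @export
merged_roc <- function(results, truth) {
  pooled <- pool_results(results, truth)
  n_pos <- sum(pooled$truth)
  n_neg <- sum(!pooled$truth)
  if (n_pos == 0L || n_neg == 0L)
    stopf("truth must contain both classes (got %d positive, %d negative)",
          n_pos, n_neg)
  ord <- order(pooled$p)
  p <- pooled$p[ord]
  tr <- pooled$truth[ord]
  last <- !duplicated(p, fromLast = TRUE)  # group ties into single steps
  tp <- cumsum(tr)[last]
  fp <- cumsum(!tr)[last]
  roc <- data.frame(specificity = c(1, 1 - fp / n_neg),
                    sensitivity = c(0, tp / n_pos))
  out <- structure(list(roc = roc, n_pos = n_pos, n_neg = n_neg),
                   class = "eval_roc")
  out$pauc <- pauc(out)
  out
}

#' @export
print.eval_roc <- function(x, ...) {
  cat(sprintf("eval_roc: %d positives, %d negatives, %d ROC points\n",
              x$n_pos, x$n_neg, nrow(x$roc)))
  cat(sprintf("normalized pAUC (specificity > 0.9): %.4f\n", x$pauc))
  invisible(x)
}

#' @export
plot.eval_roc <- function(x, spec_min = 0.9, ...) {
  plot(x$roc$specificity, x$roc$sensitivity, type = "l", xlim = c(1, 0),
       xlab = "specificity", ylab = "sensitivity",
       main = sprintf("pAUC(spec > %g) = %.3f", spec_min,
                      pauc(x, spec_min)), ...)
  abline(v = spec_min, lty = 3)
  invisible(x)
}

#' Normalized partial AUC at high specificity
#'
#' Trapezoidal area of sensitivity over specificity in `[spec_min, 1]`.  The
#' default normalization divides by the width `1 - spec_min`, so a perfect
#' method scores 1.0 and an uninformative one `(1 - spec_min) / 2` (0.05 at
#' `spec_min = 0.9`).  `method = "mcclish"` instead maps the area onto
#' `[0.5, 1]` relative to the diagonal (McClish correction).
#'
#' @param report an `eval_roc` (or a data.frame with `specificity`,
#'   `sensitivity`).
#' @param spec_min lower end of the specificity range.
#' @param method `"normalized"` (default) or `"mcclish"`.
#' @return A single number in \[0, 1\].
#' @export
pauc <- function(report, spec_min = 0.9,
                 method = c("normalized", "mcclish")) {
  method <- match.arg(method)
  roc <- if (inherits(report, "eval_roc")) report$roc else report
  # sweep order: specificity non-increasing, sensitivity non-decreasing
  # (vertical segments at equal specificity contribute zero area)
  ord <- order(-roc$specificity, roc$sensitivity)
  sp <- roc$specificity[ord]
  se <- roc$sensitivity[ord]
  if (min(sp) > spec_min) {          # curve stops early: extend flat
    sp <- c(sp, spec_min)
    se <- c(se, se[length(se)])
  } else if (!any(sp == spec_min)) { # interpolate the crossing point
    i <- min(which(sp < spec_min))   # segment (i-1, i) brackets spec_min
    se_x <- se[i - 1] + (se[i] - se[i - 1]) * (sp[i - 1] - spec_min) /
      (sp[i - 1] - sp[i])
    sp <- append(sp, spec_min, after = i - 1)
    se <- append(se, se_x, after = i - 1)
  }
  keep <- sp >= spec_min
  sp <- sp[keep]; se <- se[keep]
  area <- sum(-diff(sp) * (utils::head(se, -1) + utils::tail(se, -1)) / 2)
  width <- 1 - spec_min
  switch(method,
         normalized = area / width,
         mcclish = {
           amin <- width^2 / 2
           0.5 * (1 + (area - amin) / (width - amin))
         })
}

#' One-sided bootstrap test comparing two methods' pAUC
#'
#' Resamples proteins with replacement (stratified within true positives and
#' negatives so both classes persist), recomputes the normalized pAUC of
#' both score vectors on each resample, and reports the add-one smoothed
#' one-sided p-value `(1 + #\{pAUC_a < pAUC_b\} + 0.5 #\{ties\}) / (B + 1)`
#' for the alternative that method a outperforms method b; ties count half,
#' so identical methods give p near 0.5.
#'
#' @param scores_a,scores_b p-value vectors of the two methods on the same
#'   proteins (aligned).
#' @param truth logical vector of ground truth, aligned.
#' @param B number of bootstrap resamples.
#' @param seed integer seed.
#' @param spec_min lower end of the specificity range.
#' @return The bootstrap p-value.
#' @export
pauc_bootstrap_test <- function(scores_a, scores_b, truth, B = 1000,
                                seed = 1, spec_min = 0.9) {
  stopifnot(length(scores_a) == length(truth),
            length(scores_b) == length(truth))
  truth <- as.logical(truth)
  pos <- which(truth); neg <- which(!truth)
  if (!length(pos) || !length(neg)) stopf("truth must contain both classes")
  one <- function(scores, idx) {
    r <- merged_roc(data.frame(protein_id = seq_along(idx),
                               p = scores[idx]),
                    stats::setNames(truth[idx], seq_along(idx)))
    pauc(r, spec_min)
  }
  with_seed(seed, {
    worse <- 0
    for (b in seq_len(B)) {
      idx <- c(sample(pos, length(pos), replace = TRUE),
               sample(neg, length(neg), replace = TRUE))
      pa <- one(scores_a, idx)
      pb <- one(scores_b, idx)
      worse <- worse + (pa < pb) + 0.5 * (pa == pb)
    }
    (1 + worse) / (B + 1)
  })
}

#' True/false positive counts along an FDR threshold sweep
#'
#' @param results a `protein_de` fit or data.frame with `protein_id` and
#'   `fdr`.
#' @param truth logical vector named by protein (or data.frame with
#'   `protein_id`, `is_differential`).
#' @param thresholds FDR threshold grid.
#' @return data.frame with `threshold`, `tp`, `fp`.
#' @export
tp_fp_curves <- function(results, truth, thresholds = seq(0, 1, by = 0.01)) {
  if (inherits(results, "protein_de")) results <- results$table
  flag <- if (is.data.frame(truth))
    stats::setNames(as.logical(truth$is_differential), truth$protein_id)
  else stats::setNames(as.logical(truth), names(truth))
  tr <- flag[results$protein_id]
  if (any(is.na(tr))) stopf("truth missing for some proteins")
  data.frame(threshold = thresholds,
             tp = vapply(thresholds,
                         function(t) sum(results$fdr <= t & tr), integer(1)),
             fp = vapply(thresholds,
                         function(t) sum(results$fdr <= t & !tr), integer(1)))
}

#' Proportion of full-data detections recovered in a subset run
#'
#' @param full protein identifiers detected in the full dataset.
#' @param subset_run protein identifiers detected in the subset run.
#' @return `|full intersect subset| / |full|`; 0 (with a warning) if `full`
#'   is empty.
#' @export
detection_overlap <- function(full, subset_run) {
  if (length(full) == 0L) {
    warning("no detections in the full run; overlap set to 0", call. = FALSE)
    return(0)
  }
  length(intersect(full, subset_run)) / length(unique(full))
}

#' Replicated-detection filter across two runs
#'
#' Keeps proteins detected (FDR at most `fdr_max`) in both runs, quantified
#' with more than `min_peptides` peptides in both, and whose fold changes
#' point in the same (nonzero) direction in both — the standard filter for
#' calling a detection replicated across visits.
#'
#' @param run1,run2 `protein_de` fits or data.frames with `protein_id`,
#'   `fdr`, `n_peptides`, `slr`.
#' @param fdr_max detection threshold.
#' @param min_peptides single-peptide proteins are dropped at the default 1.
#' @return Character vector of surviving protein identifiers.
#' @export
filter_detections <- function(run1, run2, fdr_max = 0.05, min_peptides = 1) {
  get <- function(x) if (inherits(x, "protein_de")) x$table else x
  r1 <- get(run1); r2 <- get(run2)
  common <- intersect(r1$protein_id, r2$protein_id)
  i1 <- match(common, r1$protein_id)
  i2 <- match(common, r2$protein_id)
  keep <- r1$fdr[i1] <= fdr_max & r2$fdr[i2] <= fdr_max &
    r1$n_peptides[i1] > min_peptides & r2$n_peptides[i2] > min_peptides &
    sign(r1$slr[i1]) == sign(r2$slr[i2]) & sign(r1$slr[i1]) != 0
  common[keep]
}

#' Composition of the two-proteome hybrid mixture
#'
#' The organism fractions of the two benchmark samples (constant human
#' background, E. coli up, yeast down), shipped as a plain-text table with
#' the package.
#'
#' @return data.frame with columns `organism`, `sample_A`, `sample_B`
#'   (fractions summing to 1 per sample).
#' @export
hybrid_composition <- function() {
  path <- system.file("extdata", "hybrid_composition.tsv",
                      package = "ropeca", mustWork = TRUE)
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}

#' Fraction of the mixture that is differential between two samples
#'
#' Sums the mixture fractions of the organisms whose proportion differs
#' between the two samples — the expected fraction of truly differential
#' proteins in a hybrid-proteome benchmark.
#'
#' @param composition data.frame as returned by [hybrid_composition()].
#' @return The differential fraction (a number in \[0, 1\]).
#' @export
differential_fraction <- function(composition = hybrid_composition()) {
  d <- composition$sample_A != composition$sample_B
  fa <- sum(composition$sample_A[d])
  fb <- sum(composition$sample_B[d])
  if (abs(fa - fb) > 1e-12)
    warning(sprintf("differential fractions differ between samples (%g vs %g)",
                    fa, fb), call. = FALSE)
  fa
}
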