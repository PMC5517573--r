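make_scores <- function(n_pos, n_neg, sep = TRUE, seed = 1) {
  set.seed(seed)
  truth <- c(rep(TRUE, n_pos), rep(FALSE, n_neg))
  p <- if (sep) c(runif(n_pos, 0, 1e-4), runif(n_neg, 0.2, 1))
       else runif(n_pos + n_neg)
  list(res = data.frame(protein_id = paste0("P", seq_along(truth)), p = p,
                        fdr = bh_fdr(p)),
       truth = stats::setNames(truth, paste0("P", seq_along(truth))))
}

test_that("the merged ROC is exact on separable, random and duplicated input", {
  sep <- make_scores(20, 80)
  roc <- merged_roc(sep$res, sep$truth)
  expect_equal(roc$pauc, 1)                    # perfect separation
  expect_equal(max(roc$roc$sensitivity[roc$roc$specificity == 1]), 1)

  rnd <- make_scores(500, 1500, sep = FALSE, seed = 2)
  expect_equal(merged_roc(rnd$res, rnd$truth)$pauc, 0.05, tolerance = 0.4)

  # merging a comparison with itself reproduces the single-copy curve
  dup <- merged_roc(list(sep$res, sep$res), list(sep$truth, sep$truth))
  single <- merged_roc(sep$res, sep$truth)
  expect_equal(dup$roc, single$roc)
  expect_equal(dup$pauc, single$pauc)

  one_class <- data.frame(protein_id = c("P1", "P2"), p = c(0.1, 0.2))
  expect_error(merged_roc(one_class, c(P1 = TRUE, P2 = TRUE)), "both classes")
})

test_that("partial AUC integrates hand geometry and normalizations", {
  # flat curve at sensitivity 0.5 over the whole specificity range
  flat <- data.frame(specificity = c(1, 1, 0), sensitivity = c(0, 0.5, 0.5))
  expect_equal(pauc(flat), 0.5)
  # hand-drawn three-point curve: sens rises 0->1 linearly over spec 1->0.8;
  # area over [0.9, 1]: triangle with height 0.5 -> 0.025; /0.1 = 0.25
  tri <- data.frame(specificity = c(1, 0.8, 0), sensitivity = c(0, 1, 1))
  expect_equal(pauc(tri), 0.25)
  # McClish correction maps the diagonal to 0.5 and perfection to 1
  diag <- data.frame(specificity = c(1, 0), sensitivity = c(0, 1))
  expect_equal(pauc(diag, method = "mcclish"), 0.5)
  perfect <- data.frame(specificity = c(1, 1, 0), sensitivity = c(0, 1, 1))
  expect_equal(pauc(perfect, method = "mcclish"), 1)
  expect_equal(pauc(perfect), 1)
})

test_that("pAUC is invariant to strictly monotone score transforms", {
  x <- make_scores(30, 120, sep = FALSE, seed = 3)
  r1 <- merged_roc(x$res, x$truth)
  trans <- x$res
  trans$p <- stats::plogis(5 * (trans$p - 0.2))  # strictly increasing
  r2 <- merged_roc(trans, x$truth)
  expect_equal(r1$pauc, r2$pauc, tolerance = 1e-12)
  expect_equal(r1$roc, r2$roc)
})

test_that("pAUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  x <- make_scores(40, 160, sep = FALSE, seed = 4)
  ours <- merged_roc(x$res, x$truth)
  ref <- pROC::roc(response = x$truth, predictor = -x$res$p,
                   direction = "<", quiet = TRUE)
  ref_pauc <- as.numeric(pROC::auc(ref, partial.auc = c(1, 0.9),
                                   partial.auc.focus = "specificity",
                                   partial.auc.correct = FALSE)) / 0.1
  expect_equal(ours$pauc, ref_pauc, tolerance = 1e-8)
})

test_that("the bootstrap pAUC test behaves at both extremes", {
  x <- make_scores(40, 160, sep = FALSE, seed = 5)
  p_self <- pauc_bootstrap_test(x$res$p, x$res$p, x$truth, B = 200, seed = 6)
  expect_equal(p_self, (1 + 100) / 201)        # every resample ties: p ~ 0.5
  good <- make_scores(40, 160, sep = TRUE, seed = 7)
  p_win <- pauc_bootstrap_test(good$res$p, runif(200), good$truth,
                               B = 200, seed = 8)
  expect_lte(p_win, 2 / 201)
  expect_identical(p_win, pauc_bootstrap_test(good$res$p, runif(200),
                                              good$truth, B = 200, seed = 8))
})

test_that("TP/FP curves count detections along the threshold sweep", {
  res <- data.frame(protein_id = paste0("P", 1:5),
                    p = c(0.001, 0.01, 0.02, 0.5, 0.9),
                    fdr = c(0.005, 0.025, 0.04, 0.62, 0.9))
  truth <- stats::setNames(c(TRUE, TRUE, FALSE, TRUE, FALSE),
                           paste0("P", 1:5))
  cv <- tp_fp_curves(res, truth, thresholds = c(0, 0.03, 0.05, 1))
  expect_identical(cv$tp, c(0L, 2L, 2L, 3L))
  expect_identical(cv$fp, c(0L, 0L, 1L, 2L))
  # counts are non-decreasing and sum to total detections
  expect_true(all(diff(cv$tp) >= 0) && all(diff(cv$fp) >= 0))
  expect_identical(cv$tp + cv$fp,
                   vapply(c(0, 0.03, 0.05, 1),
                          function(t) sum(res$fdr <= t), integer(1)))
})

test_that("detection overlap is the recovered fraction of full-data hits", {
  expect_equal(detection_overlap(c("A", "B", "C"), c("B", "C", "D")), 2 / 3)
  expect_equal(detection_overlap(c("A", "B"), c("A", "B")), 1)
  expect_equal(detection_overlap(c("A", "B"), c("X", "Y")), 0)
  expect_warning(ov <- detection_overlap(character(0), c("A")), "no detections")
  expect_equal(ov, 0)
})

test_that("the replicated-detection filter applies all three rules", {
  r1 <- data.frame(protein_id = paste0("P", 1:6),
                   fdr = c(0.01, 0.01, 0.01, 0.2, 0.01, 0.01),
                   n_peptides = c(3, 1, 4, 5, 2, 3),
                   slr = c(1.2, 0.8, -0.5, 1.0, 0.6, 0))
  r2 <- data.frame(protein_id = paste0("P", 1:6),
                   fdr = c(0.02, 0.03, 0.04, 0.01, 0.04, 0.01),
                   n_peptides = c(4, 2, 4, 5, 3, 3),
                   slr = c(0.9, 0.7, 0.6, 1.1, 0.5, 0.2))
  # P1 passes; P2 single-peptide in run 1; P3 sign flip; P4 fails FDR in run
  # 1; P5 passes; P6 zero slr in run 1
  expect_setequal(filter_detections(r1, r2), c("P1", "P5"))
  expect_setequal(filter_detections(r1, r2, min_peptides = 2), "P1")
  expect_identical(filter_detections(r1, r2, min_peptides = 3), character(0))
})

test_that("the shipped hybrid composition yields the 35% differential fraction", {
  comp <- hybrid_composition()
  expect_identical(nrow(comp), 3L)
  expect_equal(sum(comp$sample_A), 1)
  expect_equal(sum(comp$sample_B), 1)
  expect_equal(differential_fraction(comp), 0.35)
})

test_that("mock splits of null data keep the realized FDP conservative", {
  st <- simulate_spikein(sim_config(n_background = 150, n_spike = 0,
                                    peptides_per_protein = 3,
                                    n_per_group = 5, seed = 301))
  m <- median_normalize(st$matrix)
  fdp <- vapply(1:100, function(s) {
    ms <- mock_split(m, seed = 300 + s)
    fit <- peca(ms)                      # every detection is false
    n_det <- sum(fit$table$fdr <= 0.05)
    if (n_det == 0) 0 else 1
  }, numeric(1))
  expect_lte(mean(fdp), 0.05 + 1e-9)
})
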