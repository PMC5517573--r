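#' Configuration of the synthetic benchmark generators
#'
#' Describes a two-group label-free quantification experiment on the log2
#' scale: a constant background of proteins plus a set of spiked (truly
#' differential) proteins with known log2 fold changes.  Defaults emulate a
#' spike-in profiling standard: 12 spiked proteins in a constant background,
#' three replicates per group, adjacent concentration steps of roughly
#' 1.1-fold, 0.63-fold and 4-fold for the three spike mixes.
#'
#' The signal model per peptide j of protein g in sample s of group 2 is
#' `base_g + offset_j + fc_g + noise` with `base_g ~ N(protein_base_mean,
#' protein_base_sd)`, `offset_j ~ N(0, peptide_offset_sd)` (ionization
#' efficiency spread), and `noise ~ N(0, peptide_noise_sd)`; group 1 omits
#' `fc_g`.  Missingness is completely at random at `missing_rate`, or
#' abundance-driven (logistic in the latent log2 value) when
#' `missing_mode = "intensity"`.
#'
#' @param n_background number of non-differential background proteins.
#' @param n_spike number of truly differential proteins.
#' @param log2_fc log2 fold change(s) applied to group 2 of the spiked
#'   proteins; recycled across spikes.
#' @param peptides_per_protein mean peptide count per protein (counts are
#'   `1 + Poisson(mean - 1)`, so at least 1).
#' @param n_per_group samples per group.
#' @param peptide_noise_sd residual SD in log2 units.
#' @param protein_base_mean,protein_base_sd protein baseline abundance
#'   distribution (log2).
#' @param peptide_offset_sd SD of the per-peptide additive offset (log2).
#' @param missing_rate fraction of values set missing, in \[0, 1).
#' @param missing_mode `"mcar"` (default) or `"intensity"` (lower-abundance
#'   values more likely missing).
#' @param seed integer seed.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_background = 100, n_spike = 12,
                       log2_fc = rep(c(log2(1.1), log2(0.63), 2), each = 4),
                       peptides_per_protein = 5, n_per_group = 3,
                       peptide_noise_sd = 0.3,
                       protein_base_mean = 20, protein_base_sd = 2,
                       peptide_offset_sd = 1,
                       missing_rate = 0, missing_mode = c("mcar", "intensity"),
                       seed = 1) {
  missing_mode <- match.arg(missing_mode)
  cfg <- list(n_background = as.integer(n_background),
              n_spike = as.integer(n_spike),
              log2_fc = as.numeric(log2_fc),
              peptides_per_protein = peptides_per_protein,
              n_per_group = as.integer(n_per_group),
              peptide_noise_sd = peptide_noise_sd,
              protein_base_mean = protein_base_mean,
              protein_base_sd = protein_base_sd,
              peptide_offset_sd = peptide_offset_sd,
              missing_rate = missing_rate, missing_mode = missing_mode,
              seed = as.integer(seed))
  with(cfg, {
    if (n_background < 0 || n_spike < 0 || n_background + n_spike < 1)
      stopf("need a positive number of proteins")
    if (n_per_group < 2) stopf("n_per_group must be >= 2")
    if (peptides_per_protein < 1) stopf("peptides_per_protein must be >= 1")
    if (missing_rate < 0 || missing_rate >= 1)
      stopf("missing_rate must be in [0, 1)")
    if (peptide_noise_sd <= 0 || protein_base_sd < 0 || peptide_offset_sd < 0)
      stopf("invalid dispersion parameters")
  })
  structure(cfg, class = "sim_config")
}

# core generator shared by the spike-in and hybrid designs
simulate_matrix <- function(cfg, fc_per_protein) {
  n_prot <- cfg$n_background + cfg$n_spike
  protein_id <- sprintf("PROT%04d", seq_len(n_prot))
  with_seed(cfg$seed, {
    npep <- 1L + stats::rpois(n_prot, cfg$peptides_per_protein - 1)
    base <- stats::rnorm(n_prot, cfg$protein_base_mean, cfg$protein_base_sd)
    F <- sum(npep)
    prot_of_pep <- rep(seq_len(n_prot), npep)
    offset <- stats::rnorm(F, 0, cfg$peptide_offset_sd)
    n <- 2L * cfg$n_per_group
    group <- rep(c("A", "B"), each = cfg$n_per_group)
    mu <- base[prot_of_pep] + offset
    X <- matrix(stats::rnorm(F * n, sd = cfg$peptide_noise_sd), F, n)
    X <- X + mu
    X[, group == "B"] <- X[, group == "B"] + fc_per_protein[prot_of_pep]
    if (cfg$missing_rate > 0) {
      if (cfg$missing_mode == "mcar") {
        drop <- matrix(stats::runif(F * n) < cfg$missing_rate, F, n)
      } else {
        # logistic in the latent abundance, centered so the marginal rate
        # matches missing_rate; slope 1 per log2 unit
        ctr <- stats::quantile(X, probs = 1 - cfg$missing_rate)
        pr <- stats::plogis(-(X - ctr))
        pr <- pmin(pr * (cfg$missing_rate / mean(pr)), 1)
        drop <- matrix(stats::runif(F * n) < pr, F, n)
      }
      X[drop] <- NA_real_
    }
    dimnames(X) <- list(sprintf("%s_pep%02d", protein_id[prot_of_pep],
                                sequence(npep)),
                        sprintf("%s%d", group, sequence(rep(cfg$n_per_group, 2))))
    m <- peptide_matrix(X, protein = protein_id[prot_of_pep], group = group)
    structure(list(matrix = m,
                   is_differential = stats::setNames(fc_per_protein != 0,
                                                     protein_id),
                   true_log2_fc = stats::setNames(fc_per_protein, protein_id),
                   config = cfg),
              class = "sim_truth")
  })
}

#' @export
print.sim_truth <- function(x, ...) {
  cat(sprintf("sim_truth: %d proteins (%d differential), %d peptides, %d+%d samples\n",
              length(x$is_differential), sum(x$is_differential),
              nrow(x$matrix$abundance), sum(x$matrix$group == levels(x$matrix$group)[1]),
              sum(x$matrix$group == levels(x$matrix$group)[2])))
  invisible(x)
}

#' Simulate a spike-in benchmark
#'
#' A constant background of null proteins plus `n_spike` proteins shifted in
#' group "B" by the configured log2 fold changes, with multiple peptides per
#' protein, log-normal (Gaussian on log2) noise and optional missing values.
#' Deterministic given `cfg$seed`.
#'
#' @param cfg a [sim_config].
#' @return A `sim_truth`: `$matrix` ([peptide_matrix]), `$is_differential`
#'   and `$true_log2_fc` named per protein, `$config`.
#' @export
simulate_spikein <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  fc <- c(rep(0, cfg$n_background),
          rep_len(cfg$log2_fc, cfg$n_spike))
  simulate_matrix(cfg, fc)
}

#' Simulate a hybrid-proteome benchmark
#'
#' Mimics mixing whole proteomes in different ratios between two samples so
#' that a stated fraction of all proteins is truly differential, with
#' up- and down-regulated subsets (defaults +2 and -1 in log2, the
#' adjacent-sample ratios of an E. coli-up / yeast-down two-proteome mix).
#' The total protein count is `cfg$n_background + cfg$n_spike`; the
#' differential count is `round(fraction_differential * total)`, split
#' evenly (up first) across `fc_mix`.
#'
#' @param cfg a [sim_config]; its `n_background`/`n_spike` fix the total
#'   protein count.
#' @param fraction_differential fraction of proteins that are differential,
#'   in (0, 1); 0 is allowed and yields a pure null.
#' @param fc_mix log2 fold changes assigned to the differential proteins.
#' @return A `sim_truth`.
#' @export
simulate_hybrid <- function(cfg = sim_config(), fraction_differential = 0.35,
                            fc_mix = c(2, -1)) {
  stopifnot(inherits(cfg, "sim_config"))
  if (fraction_differential < 0 || fraction_differential >= 1)
    stopf("fraction_differential must be in [0, 1)")
  total <- cfg$n_background + cfg$n_spike
  n_diff <- as.integer(round(fraction_differential * total))
  cnt <- diff(round(seq(0, n_diff, length.out = length(fc_mix) + 1)))
  fc <- c(rep(0, total - n_diff), rep(fc_mix, cnt))
  cfg$n_background <- total - n_diff
  cfg$n_spike <- n_diff
  simulate_matrix(cfg, fc)
}

#' Random mock split into two artificial groups
#'
#' Ignores the original design and partitions the samples uniformly at
#' random into two equal (+/- 1) artificial groups, "M1" and "M2".  Testing
#' differential expression between them estimates the empirical false
#' discovery rate, since no protein is truly differential between random
#' halves.
#'
#' @param m a [peptide_matrix] with >= 4 samples.
#' @param seed integer seed.
#' @return A [peptide_matrix] with the artificial design.
#' @export
mock_split <- function(m, seed) {
  n <- ncol(m$abundance)
  if (n < 4L) stopf("mock_split needs >= 4 samples")
  with_seed(seed, {
    half <- sample.int(n, n %/% 2)
    grp <- ifelse(seq_len(n) %in% half, "M1", "M2")
    peptide_matrix(m$abundance, m$protein, grp)
  })
}

#' Thin one group to a random subset of its samples
#'
#' Retains a without-replacement random subset of the named group and all
#' samples of the other group(s), as in subset-reproducibility analyses.
#'
#' @param m a [peptide_matrix].
#' @param group_to_thin group label to subsample.
#' @param size number of samples to keep in that group.
#' @param seed integer seed.
#' @return A [peptide_matrix].
#' @export
subsample_individuals <- function(m, group_to_thin, size, seed) {
  pos <- which(m$group == group_to_thin)
  if (length(pos) == 0L) stopf("unknown group: %s", group_to_thin)
  if (size > length(pos))
    stopf("size %d exceeds group size %d", size, length(pos))
  with_seed(seed, {
    keep <- sort(c(which(m$group != group_to_thin), sample(pos, size)))
    peptide_matrix(m$abundance[, keep, drop = FALSE], m$protein,
                   droplevels(m$group[keep]))
  })
}

#' Write a simulation to peptide/design/truth TSV files
#'
#' @param truth a `sim_truth`.
#' @param dir output directory (created if needed).
#' @return Named character vector of the three paths, invisibly.
#' @export
write_simulation <- function(truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(peptides = file.path(dir, "peptides.tsv"),
             design = file.path(dir, "design.tsv"),
             truth = file.path(dir, "truth.tsv"))
  write_peptide_table(truth$matrix, paths["peptides"], paths["design"])
  con <- file(paths["truth"], "w")
  on.exit(close(con))
  writeLines(sprintf("# seed: %d", truth$config$seed), con)
  utils::write.table(
    data.frame(protein_id = names(truth$is_differential),
               is_differential = truth$is_differential,
               true_log2_fc = truth$true_log2_fc),
    con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(paths)
}

#' Read a simulation truth table
#'
#' @param path TSV written by [write_simulation()] (leading `#` comment
#'   lines are skipped).
#' @return data.frame with `protein_id`, `is_differential`, `true_log2_fc`.
#' @export
read_truth_table <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE)
}
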