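# small in-code fixtures shared across test files

# deterministic toy matrix: `npep` peptides per protein, Gaussian noise
make_toy_matrix <- function(n_protein = 5, npep = 3, n_per_group = 3,
                            fc = 0, noise_sd = 0.5, seed = 42) {
  cfg <- sim_config(n_background = n_protein, n_spike = 0,
                    peptides_per_protein = npep, n_per_group = n_per_group,
                    peptide_noise_sd = noise_sd, seed = seed)
  st <- if (fc == 0) simulate_spikein(cfg) else {
    cfg$n_spike <- n_protein %/% 2
    cfg$n_background <- n_protein - cfg$n_spike
    cfg$log2_fc <- fc
    simulate_spikein(cfg)
  }
  st$matrix
}

# write a peptide matrix + design to temp TSVs, return the two paths
write_temp_tables <- function(m, dir = withr::local_tempdir(.local_envir =
                                                              parent.frame())) {
  paths <- c(peptides = file.path(dir, "peptides.tsv"),
             design = file.path(dir, "design.tsv"))
  write_peptide_table(m, paths["peptides"], paths["design"])
  paths
}

# grid used for the larger simulation-based checks: coarser alpha1 lattice
# and fewer resamples than the package defaults, sized for quick runs
test_grid <- function(seed, n_bootstrap = 50, n_permutation = 400,
                      alpha1 = seq(0, 5, by = 0.1), ...) {
  rots_grid(alpha1 = alpha1, n_bootstrap = n_bootstrap,
            n_permutation = n_permutation, seed = seed, ...)
}
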