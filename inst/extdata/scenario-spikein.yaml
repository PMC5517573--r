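# Spike-in-like benchmark: a constant background plus 12 spiked proteins in
# three mixes whose adjacent concentration steps are ~1.1-fold, ~0.63-fold
# and 4-fold (log2: 0.1375, -0.6666, 2).
design: spikein
n_background: 100
n_spike: 12
log2_fc: [0.1375, 0.1375, 0.1375, 0.1375,
          -0.6666, -0.6666, -0.6666, -0.6666,
          2, 2, 2, 2]
peptides_per_protein: 5
n_per_group: 3
peptide_noise_sd: 0.3
protein_base_mean: 20
protein_base_sd: 2
peptide_offset_sd: 1
missing_rate: 0
seed: 1
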