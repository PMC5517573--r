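# Hybrid-proteome-like benchmark: 35% of 200 proteins differential, split
# between a 4-fold up subset (log2 +2) and a 2-fold down subset (log2 -1),
# mimicking an E. coli-up / yeast-down two-proteome mixture over a constant
# human background.
design: hybrid
n_background: 188
n_spike: 12
fraction_differential: 0.35
fc_mix: [2, -1]
peptides_per_protein: 5
n_per_group: 3
peptide_noise_sd: 0.4
protein_base_mean: 20
protein_base_sd: 2
peptide_offset_sd: 1
missing_rate: 0
seed: 1
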