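{
  "config": {
    "seed": 42,
    "n_chroms": 2,
    "chrom_len_bp": 2000000,
    "chip_bin_bp": 5000,
    "hic_bin_bp": 100000,
    "compartment_block_bp": 500000,
    "frac_lad_in_B": 0.8,
    "gsr_frac_of_A": 0.6,
    "gsr_frac_of_B": 0.1,
    "erasure_depth": 1,
    "noise_sd": 0.3,
    "checkerboard_contrast": 1.5,
    "contrast_treated": 1.7,
    "decay_exponent": 1,
    "hic_depth": 200,
    "hic_lognorm_sd": 0.2,
    "hic_masked_frac": 0.02,
    "n_genes": 120,
    "frac_de_up_in_gsr": 0.3,
    "frac_de_up_bg": 0.02,
    "frac_de_down": 0.06,
    "gene_density_ratio_A": 3,
    "damid_noise_sd": 0.3,
    "gsr_ilad_detach": 0.3,
    "atac_fold_up": 2
  },
  "chrom_lengths": {
    "chr1": 2000000,
    "chr2": 2000000
  },
  "coverage": {
    "gsr": 0.35,
    "lad_control": 0.5,
    "lad_treated": 0.38219425,
    "compartment_A": 0.5
  }
}
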