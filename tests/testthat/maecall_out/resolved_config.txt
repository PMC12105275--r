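outdir = maecall_out
seed = 1
level = GENE
quiet = FALSE
cn_loss_threshold = 1.5
expr_cutoff = -0.5
wes_cov_cutoff = -0.5
min_cells_flip = 6
min_per_arm = 3
min_corr_n = 10
fdr_levels = 0.05,0.125
n_samples = 40
n_genes = 60
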