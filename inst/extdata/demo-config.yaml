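# Demo pipeline configuration: one synthetic contrast-enhanced scan plus a
# 17 + 17 matched cohort, analyzed end to end.
seed: 1
outdir: spineqct-demo
noise_sd: 15
hu_offset: 0
n_per_group: 17
rho: 0.7
p_enter: 0.05
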