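# Example pipeline config (flat key: value, a YAML subset).
# Synthetic two-population study with planted tracts and a planted sweep.
seed: 1
stages: qc,structure,roh,selection
synthetic: true
n_pops: 2
samples_per_pop: 80
n_snps: 12000
fst: 0.003
inbreeding_f: 0.01
# QC thresholds
min_call_rate: 0.98
min_maf: 0.01
hwe_alpha: 0.001
hwe_method: exact
# RoH caller
window_snps: 50
window_span_kb_cap: 5000
max_het_per_window: 1
max_missing_per_window: 5
hit_proportion_threshold: 0.05
min_segment_kb: 500
min_segment_snps: 50
accessible_gb: 2.84
# selection scan
sel_n_snps: 10000
sel_samples: 50
sel_derived_freq: 0.7
sel_window_kb: 100
sel_threshold: 4
sel_n_perm: 1000
sel_min_maf: 0.05
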