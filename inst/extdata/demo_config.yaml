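# Reduced-size synthetic cohort-audit demo: same structure as the full
# default study (26 populations, 8:1 imbalance, three-way admixture), at a
# variant count and population scale that completes in a few minutes.
seed: 20260921
out_dir: "admixaudit_demo"
m: 4000
pop_scale: 0.5
B: 20
k: 2
miss_rate: 0.01
err_rate: 0.0059
R_err: 0.4
discovery_ancestry: "EUR"
discovery_n: 120
maf_cutoff: 0.05
stages: ["simulate", "qc", "ascertain", "validate", "structure"]
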