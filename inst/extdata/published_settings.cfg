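min_cluster_size=200
min_frac5=0.75
min_frac3=0.75
identity=0.99
max_mismatch=1
seed_start=4
seed_end=10
forced_helix_start=3
forced_helix_end=10
min_matches=11
max_ddG=-9
max_dG=-20
context=30
flank5=3
flank3=15
fold_window=140
window_size=10
window_step=5
pre_length=70
fold_temperature=25
species_tag=SySp
sex_tag=F
seed=1
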