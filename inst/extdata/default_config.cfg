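hr_len = 100
hr3_len = 40
hr3_min = 30
hr3_max = 50
frag_len = 200
n_terminators = 2
w_max = 14
w_integration = 20
p_threshold = 0.9
rbs_consensus = "AGGAGG"
rbs_spacer_min = 4
rbs_spacer_max = 13
hairpin_min_stem = 8
hairpin_loop_min = 3
hairpin_loop_max = 10
overlap_len = 20
tm_target = 60
tm_delta = 3
primer_min_len = 18
primer_max_len = 35
tm_na_mM = 200
tm_primer_nM = 250
marker = "cat"
cat_orf_gap = 0
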