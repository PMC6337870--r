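param	value
D_m2_per_s	2.567e-12
k_diss_per_s	1
max_rate_aa_per_s	24
burn_in_steps	1000
stop_steps	5000
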