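formula,sq_sum_epsilon_N
CuO,9.93
Sb2O3,0.018
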