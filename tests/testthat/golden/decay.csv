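origin,amplitude,exponent,r_squared,n_pairs,fallback
C01,60.33852574788996,1.0601833456010938,0.73065496031506494,35,0
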