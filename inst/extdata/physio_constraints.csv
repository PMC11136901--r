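predictor,opt_lo,opt_hi,hard_limit,limit_side,edges
temp_mean,15,18,26,upper,free_within
depth,0,40,200,upper,fixed
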