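cohort,c0,c1,c2
alive,27,52,45
dead_sampled,72,51,10
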