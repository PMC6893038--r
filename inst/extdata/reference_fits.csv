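group,a,b,c,adj_r2
non_gamified,17.3,0.270,23.6,0.973
gamified,15.7,0.320,32.5,0.771
active_gamified,20.7,0.710,20.4,0.970
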