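distance_km,fraction,population
0,0.314,1685420
20,0.747,4009582
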