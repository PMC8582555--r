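{"q0": 1.037, "k1_e3": 7.275, "k2_e5": -2.296, "p0_e3": 3.088, "pstar_e3": 30.68}
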