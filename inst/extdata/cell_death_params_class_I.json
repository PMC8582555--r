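{"q0": 1.090, "k1_e3": 5.917, "k2_e5": -1.879, "p_e3": 9.944}
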