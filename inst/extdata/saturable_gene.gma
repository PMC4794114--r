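bounds: a1 -6 6
bounds: g1 -6 6
bounds: K1 -6 6
X1' = a1*d1^-1 - g1*X1
0 = 1 + K1^-2*X1^2 - d1
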