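bounds: a1 -6 6
bounds: a3 -6 6
bounds: g1 -6 6
bounds: g2 -6 6
bounds: g3 -6 6
bounds: g4 -6 6
bounds: k2 -6 6
bounds: k4 -6 6
bounds: KA1 -6 6
bounds: KA3 -6 6
bounds: KR1 -6 6
bounds: rA1 0 6
bounds: rA3 0 6
X1' = a1*d1^-1 + a1*KA1^-2*rA1*X2^2*d1^-1 + a1*KR1^-2*X4^2*d1^-1 - g1*X1
X2' = k2*X1 - g2*X2
X3' = a3*d3^-1 + a3*KA3^-4*rA3*X2^4*d3^-1 - g3*X3
X4' = k4*X3 - g4*X4
0 = 1 + KA1^-2*X2^2 + KR1^-2*X4^2 - d1
0 = 1 + KA3^-4*X2^4 - d3
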