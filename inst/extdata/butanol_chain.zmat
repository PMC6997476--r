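# heavy-atom model chain with three target torsions (butanol-like backbone)
C
C 1 B1
C 2 B2 1 A1
C 3 B3 2 A2 1 PHI1
C 4 B4 3 A3 2 PHI2
O 5 B5 4 A4 3 PHI3
Variables:
B1 1.526
B2 1.526
B3 1.526
B4 1.526
B5 1.43
A1 115.0
A2 115.0
A3 115.0
A4 111.0
PHI1 180.0
PHI2 180.0
PHI3 180.0
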