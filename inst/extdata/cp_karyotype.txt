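# Block composition of the 15 Catolobus pendulus chromosomes (Cp1-Cp15),
# transcribed from the painted karyotype. Tokens are derived sub-block labels
# with orientation, CEN marks the centromere, @1/@2 are homeolog copies
# (copy assignment is bookkeeping; comparisons are copy-blind).
Cp1	D+@1 CEN E+@1
Cp2	D+@2 CEN E+@2
Cp3	F+@1 CEN G+@1 H+@1
Cp4	I+@1 CEN J+@1
Cp5	I+@2 CEN J+@2
Cp6	(K-L)+@1 CEN (M-N)+@1
Cp7	O+@1 P+@1 CEN Q+@1 R+@1
Cp8	S+@1 T+@1 CEN U+@1
Cp9	V+@1 CEN W+@1 X+@1
Cp10	V+@2 CEN W+@2 X+@2
Cp11	Aa+@1 Ca-@1 CEN B-@1 Ab-@1 Cb+@1
Cp12	Ab+@2 B+@2 CEN C+@2
Cp13	Aa+@2 O+@2 P+@2 CEN Q+@2 R+@2
Cp14	U-@2 Fb+@2 Ha-@2 G-@2 CEN Fc-@2 Hb+@2
Cp15	Fa+@2 T-@2 S-@2 (K-L)+@2 CEN (M-N)+@2
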