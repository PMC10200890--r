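chromosome	arm	blocks
AK1	upper	A,B
AK1	lower	C
AK2	upper	D
AK2	lower	E
AK3	upper	F
AK3	lower	G,H
AK4	upper	I
AK4	lower	J
AK5	upper	K-L
AK5	lower	M-N
AK6	upper	O,P
AK6	lower	Q,R
AK7	upper	S,T
AK7	lower	U
AK8	upper	V
AK8	lower	W,X
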