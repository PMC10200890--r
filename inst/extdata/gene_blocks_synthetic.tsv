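gene	block
gene001	A
gene002	B
gene003	C
gene004	D
gene005	E
gene006	F
gene007	G
gene008	H
gene009	I
gene010	J
gene011	K-L
gene012	M-N
gene013	O
gene014	P
gene015	Q
gene016	R
gene017	S
gene018	T
gene019	U
gene020	V
gene021	W
gene022	X
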