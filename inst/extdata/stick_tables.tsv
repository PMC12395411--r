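edge	state	site	energy_eV	strength	character
O1s	GS	O8	539.95	1.0	1s-1
O1s	GS	O7	540.05	1.0	1s-1
O1s	S1_npi	O7	539.86	1.0	1s-1 npi*
O1s	S1_npi	O8	544.02	1.0	1s-1 npi* (L)
O1s	S1_npi	O8	546.40	1.0	1s-1 npi* (H)
O1s	S2_pipi	O8	534.20	0.1	1s-1 (shake-down)
O1s	S2_pipi	O8	538.26	1.0	1s-1 pipi*
O1s	S2_pipi	O7	539.17	1.0	1s-1 pipi* (L)
O1s	S2_pipi	O7	540.41	1.0	1s-1 pipi* (H)
N1s	GS	N3	408.77	1.0	1s-1
N1s	GS	N1	409.10	1.0	1s-1
N1s	S1_npi	N3	408.58	1.0	1s-1 npi*
N1s	S1_npi	N1	408.93	1.0	1s-1 npi*
N1s	S2_pipi	N3	408.38	1.0	1s-1 pipi*
N1s	S2_pipi	N1	410.24	1.0	1s-1 pipi*
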