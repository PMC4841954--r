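pos	NC	CC	JH	SC	SW	EU	WB.S	TB
1664	C	C	C	C/T(80/4)	C	C	C	C
1818	G	G/A(31/11)	G	G/A(50/34)	G	G/A(32/1)	G	G
1993	C	C/T(22/20)	C	C/T(69/15)	C	C/T(29/4)	C	C
2020	C/T(20/3)	C/T(37/5)	C/T(21/8)	C	C	C	C/T(1/2)	C/T(26/1)
2028	G/A(20/3)	G	G	G/A(78/6)	G	G	G	G
2050	C/T(19/4)	C/T(27/15)	C	C/T(45/39)	C/T(21/2)	C/T(26/7)	C	C
2292	C/T(21/2)	C/T(36/6)	C/T(18/11)	C/T(81/3)	C/T(19/4)	C	C	C
2456	C	C	C/T(26/3)	C/T(78/6)	C	C	C	C
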