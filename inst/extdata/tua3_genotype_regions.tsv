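genotype	region	n
U1	SE Turkey	1
U2	Iraq	1
U2	Iran	1
U2	NE Lebanon	9
U2	Syria	1
U2	SE Turkey	23
U3	SE Turkey	5
U4	SE Turkey	7
U5	SE Turkey	9
U6	NE Lebanon	36
U6	Syria	2
U6	SE Turkey	1
U7	NE Lebanon	1
U7	SE Turkey	1
U8	NE Lebanon	15
U8	Syria	1
U9	NE Lebanon	1
U9	Syria	1
U9	SE Turkey	4
U10	Armenia	1
U10	NE Lebanon	19
U10	SE Turkey	1
U11	SE Turkey	2
U12	SE Turkey	1
U13	NE Lebanon	1
U13	SE Turkey	3
U14	SE Turkey	5
U15	Armenia	4
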