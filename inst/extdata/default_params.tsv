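residue	atom	charge	eps	sigma	mass
*	N	-0.4	NA	NA	NA
*	CA	0.05	NA	NA	NA
*	C	0.55	NA	NA	NA
*	O	-0.55	NA	NA	NA
*	OXT	-0.55	NA	NA	NA
*	CB	0	NA	NA	NA
*	NZ	0.3	NA	NA	NA
*	NE	-0.3	NA	NA	NA
*	NH1	0.3	NA	NA	NA
*	NH2	0.3	NA	NA	NA
*	OD1	-0.55	NA	NA	NA
*	OD2	-0.55	NA	NA	NA
*	OE1	-0.55	NA	NA	NA
*	OE2	-0.55	NA	NA	NA
*	OG	-0.45	NA	NA	NA
*	OG1	-0.45	NA	NA	NA
*	OH	-0.45	NA	NA	NA
*	ND1	-0.3	NA	NA	NA
*	ND2	-0.6	NA	NA	NA
*	NE1	-0.3	NA	NA	NA
*	NE2	-0.3	NA	NA	NA
*	SG	-0.1	NA	NA	NA
*	SD	-0.1	NA	NA	NA
*	P	1.1	NA	NA	NA
*	OP1	-0.7	NA	NA	NA
*	OP2	-0.7	NA	NA	NA
*	O1P	-0.7	NA	NA	NA
*	O2P	-0.7	NA	NA	NA
*	O5'	-0.45	NA	NA	NA
*	O3'	-0.45	NA	NA	NA
*	O4'	-0.35	NA	NA	NA
*	O2'	-0.45	NA	NA	NA
*	C1'	0.1	NA	NA	NA
*	C2'	0.05	NA	NA	NA
*	C3'	0.05	NA	NA	NA
*	C4'	0.05	NA	NA	NA
*	C5'	0.05	NA	NA	NA
*	N1	-0.3	NA	NA	NA
*	N3	-0.3	NA	NA	NA
*	N7	-0.3	NA	NA	NA
*	N9	-0.05	NA	NA	NA
*	N2	-0.6	NA	NA	NA
*	N4	-0.6	NA	NA	NA
*	N6	-0.6	NA	NA	NA
*	O2	-0.5	NA	NA	NA
*	O4	-0.5	NA	NA	NA
*	O6	-0.5	NA	NA	NA
element	H	0	0.0157	2	1.008
element	C	0	0.086	3.4	12.011
element	N	0	0.17	3.25	14.007
element	O	0	0.21	2.96	15.999
element	P	0	0.2	3.74	30.974
element	S	0	0.25	3.56	32.06
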