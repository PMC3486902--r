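case_id	patient_id	maternal_age	karyotype	printed_class	stage	n_samples	chromosomes_assessed	errors
1	1	26	46,XX,t(9;16)(p13.1;p11.2)	Rec	PB	3	63	1
2	2	29	46,XY,t(17;19)(q25.3;q13.1)	Rec	Bla	7	294	7
3	2	30	46,XY,t(17;19)(q25.3;q13.1)	Rec	Bla	11	462	6
4	3	30	46,XY,t(16;17)(q11;p13.3)	Rec	Bla	5	210	17
5	4	31	45,XY,der(13;14)(q10;q10)	Rob	TE	13	546	9
6	4	31	45,XY,der(13;14)(q10;q10)	Rob	TE	9	378	2
7	5	31	46,XY,t(1;2)(q23.1;q35)	Rec	TE	3	126	0
8	6	31	45,XY,der(14;21)(q10;q10)	Rob	TE	2	84	4
9	7	32	45,XY,der(13;14)(q10;q10)	Rob	Bla	4	168	10
10	5	32	46,XY,t(1;2)(q23.1;q35)	Rec	Bla	5	210	13
11	8	32	46,XY,t(1;3)(q31;p13)	Rec	TE	7	294	13
12	9	33	45,XY,der(14;21)(q10;q10)	Rob	Bla	2	84	4
13	10	33	46,XY,t(5;15)(q13.1;q21.2)/46,XX,inv(3)(q25.1;q26.2)	Rec/Inv	Bla	8	320	37
14	11	33	46,XY,t(11;22)(q23;q11.2)	Rec	TE	9	378	2
15	12	34	45,XY,der(13;15)(q10;q10)	Rob	TE	11	462	7
16	13	34	46,XY,t(13;15)(q21.3;q11.2)	Rec	Bla	3	126	2
17	14	34	45,XX,der(13;15)(q10;q10)	Rob	Bla	7	294	22
18	15	34	46,XX,t(17;18)(p11.2;p11.2)	Rec	Bla	3	126	1
19	16	34	46,XX,t(8;9)(p12;q31)	Rec	TE	5	210	3
20	17	35	46,XY,t(1;8)(q25.3;p11.2)	Rec	Bla	2	84	2
21	18	35	46,XX,t(10;16)(q11.2;p11.2)	Rec	Bla	5	210	5
22	19	35	46,XX,t(1;2)(q24;p21)	Rec	Bla	3	126	24
23	20	35	45,XY,der(13;14)(q10;q10)	Rob	Bla	7	294	23
24	21	35	46,XX,t(1;5)(p36.1;q33)	Rec	TE	5	210	1
25	21	35	46,XX,t(1;5)(p36.1;q33)	Rec	TE	4	168	2
26	22	36	46,XY,inv(8)(p21q24.1)	Inv	TE	3	132	1
27	23	36	46,XY,t(10;17)(q21.2;p11.2)	Rec	Bla	3	126	4
28	24	36	45,XY,der(13;14)(q10;q10)	Rob	Bla	2	84	10
29	25	36	46,XY,t(7;18)(p15.3;q12.2)	Rec	Bla	4	168	3
30	26	36	45,XY,der(13;14)(q10;q10)	Rob	Bla	5	210	18
31	27	36	45,XX,der(13;14)(q10;q10)	Rob	Bla	8	336	43
32	19	36	46,XX,t(1;2)(q24;p21)	Rec	TE	2	84	0
33	28	36	45,XX,der(13;14)(q10;q10)	Rob	PB	4	84	3
34	29	37	45,XX,der(13;21)(q10;q10)	Rob	Bla	6	252	22
35	29	37	45,XX,der(13;21)(q10;q10)	Rob	Bla	5	210	5
36	30	37	46,XY,t(1;3)(q31;p13)	Rec	Bla	9	378	29
37	31	37	45,XX,der(13;14)(q10;q10)	Rob	Bla	6	252	29
38	32	38	45,XY,der(14;21)(q10;q10)	Rob	Bla	2	84	2
39	33	39	45,XY,der(14;21)(q10;q10)	Rob	Bla	8	336	27
40	34	39	46,XY,t(17;21)(q21;q22)	Rec	Bla	2	84	4
41	35	40	46,XY,t(1;15)(q21p11.2)	Rec	Bla	7	294	10
42	36	40	46,XX,t(7;10)(p11.2;p11.23)	Rec	Bla	3	126	3
43	37	41	46,XY,t(5;7)(q23.2;p14)	Rec	TE	3	126	4
44	38	41	45,XX,der(13;14)(q10;q10)	Rob	TE	5	210	17
45	39	42	45,XX,der(13;14)(q10;q10)	Rob	PB	9	189	17
46	39	42	45,XX,der(13;14)(q10;q10)	Rob	PB	8	168	16
47	39	42	45,XX,der(13;14)(q10;q10)	Rob	TE	3	126	4
48	40	42	46,XX,t(4;11)(q24;q11)	Rec	Bla	5	210	22
49	41	43	46,XX,inv(5)(p13.1–q13.3)	Inv	PB	7	154	12
50	41	43	46,XX,inv(5)(p13.1–q13.3)	Inv	TE	2	88	2
51	42	36	45,XX,der(13;14)(q10;q10)	Rob	PB	4	84	3
52	42	36	45,XX,der(13;14)(q10;q10)	Rob	PB	3	63	8
53	43	26	46,XX,t(9;16)(p13.1;p11.2)	Rec	PB	3	63	0
54	44	42	45,XX,der(13;21)(q10;q10)	Rob	PB	9	189	18
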