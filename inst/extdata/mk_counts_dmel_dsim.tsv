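gene	pS	pN	dS	dN
Barren (Cap-H)	145	57	33	15
Cap-D2	565	130	39	19
Cap-D3	544	231	25	53
Cap-G	289	133	60	36
Cap-H2	99	110	43	59
Glu (SMC4)	278	119	36	30
SA	368	27	48	4
SMC1	389	18	34	2
SMC2	150	44	24	6
SMC3	375	5	32	3
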