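gene	alpha	p_value
Barren (Cap-H)	0.1352	0.7237
Cap-D2	0.5277	0.0153
Cap-D3	0.7997	9.56E-11
Cap-G	0.4863	0.0155
Cap-H2	0.1902	0.3988
Glu (SMC4)	0.4863	0.0155
SA	0.1196	0.7723
SMC1	0.2133	0.6724
SMC2	-0.1733	0.9999
SMC3	0.8506	0.0259
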