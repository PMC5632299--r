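table	category	method	K	N	n	O	E_print	p_print	FE_print
1A	Precatalytic spliceosome	ease	34	914	38	7	1.4	0.00084	5.0
1A	mRNA splicing, via spliceosome	ease	44	914	38	8	1.8	0.00087	4.4
1A	Catalytic step 2 spliceosome	ease	30	914	38	6	1.2	0.0032	4.8
1A	Protein binding	ease	81	914	38	8	3.4	0.035	2.4
1A	Protease	ease	19	914	38	4	0.8	0.038	5.1
1A	mRNA processing	ease	9	914	38	3	0.4	0.044	8.0
1B	RNA catabolic process	binomial	9	894	35	2	0.4	0.048	5.7
2A	Coiled coil	ease	223	1229	21	9	3.8	0.018	2.4
2A	Nucleus	ease	269	1229	21	9	4.6	0.048	2.0
2A	Dendrite morphogenesis	ease	21	1229	21	3	0.4	0.050	8.4
2B	Cellular component organization	binomial	113	1207	21	5	2.0	0.041	2.5
2B	Organelle organization	binomial	64	1207	21	4	1.1	0.0229	3.6
2B	Chromatin organization	binomial	18	1207	21	2	0.3	0.0387	6.4
3A	mRNA splicing, via spliceosome	ease	50	1231	54	8	2.2	0.0069	3.6
3A	Catalytic step 2 spliceosome	ease	35	1231	54	6	1.5	0.021	3.9
3A	Precatalytic spliceosome	ease	39	1231	54	6	1.7	0.033	3.5
3B	RNA localization	binomial	11	1209	53	3	0.5	0.013	6.2
3B	Death	binomial	13	1209	53	3	0.6	0.020	5.3
3B	Cell death	binomial	13	1209	53	3	0.6	0.020	5.3
3B	Apoptotic process	binomial	13	1209	53	3	0.6	0.020	5.3
3B	Negative regulation of apoptotic process	binomial	1	1209	53	1	0.04	0.043	22.8
3B	Localization	binomial	144	1209	53	12	6.3	0.020	1.9
3B	Extracellular transport	binomial	1	1209	53	1	0.04	0.043	22.8
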