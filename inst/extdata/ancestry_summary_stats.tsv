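locus	trait	variant_id	p_meta_printed	direction_printed	p_het_printed	I2_printed	AFR_AM_maf	AFR_AM_beta	AFR_AM_p	EAS_maf	EAS_beta	EAS_p	EUR_maf	EUR_beta	EUR_p
GCKR	TG	rs1260326	1.6E-42	+++++++++++	0.72	0	0.149	0.07	2.2E-08	0.484	0.06	1.5E-13	0.350	0.07	4.4E-24
PPP1R3B	HDL	rs6601299	8.8E-10	---------+-	0.16	30.6	0.121	-0.06	8.0E-08	0.052	-0.02	0.29	0.160	-0.03	1.1E-04
ABO	LDL	rs2519093	2.2E-13	+++++++++++	0.91	0	0.105	0.10	6.6E-04	0.187	0.09	5.4E-07	0.196	0.07	1.7E-05
LCAT	HDL	rs3785100	9.0E-12	-----------	0.55	0	0.217	-0.04	6.5E-07	0.096	-0.03	1.7E-03	0.155	-0.03	1.6E-04
ABCA1	HDL	rs1883025	4.3E-17	-+---------	0.63	0	0.336	-0.02	0.018	0.271	-0.04	3.7E-11	0.209	-0.03	4.5E-07
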