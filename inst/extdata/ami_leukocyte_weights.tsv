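gene	SVM	RF	NN	GBM	DT	LASSO	Overall
ASGR2	1	1	0.97	0.21	1	0.61	4.79
SOCS3	0.98	0.34	0.52	0.24	0.59	0.61	3.28
AQP9	0.61	0.1	0.68	1	0	0.52	2.91
PPARG	0.76	0.15	1	0.25	0	0.5	2.66
RNASE1	0.74	0.22	0.24	0.1	0.41	0.74	2.45
DYSF	0.2	0.68	0.01	0.57	0	0.72	2.18
S100A9	0.53	0.09	0.01	0.74	0	0.63	2
FCGR1A	0.17	0.51	0	0.57	0	0.68	1.93
VSIG4	0.44	0.3	0.1	0.19	0.01	0.86	1.9
STAB1	0.47	0.58	0.05	0.14	0	0.61	1.85
MYBL1	0.68	0.15	0.2	0	0.26	0.52	1.81
KLRD1	0.26	0.65	0.01	0.05	0	0.73	1.7
ECRP	0.44	0.24	0.11	0	0.34	0.54	1.67
TCN2	0.46	0.27	0.07	0	0	0.78	1.58
FAM20A	0.31	0.08	0.15	0	0	1	1.54
MERTK	0.19	0.21	0.01	0.1	0.14	0.71	1.36
HP	0.09	0.78	0	0	0	0.45	1.32
RNASE2	0.16	0.42	0.01	0	0	0.7	1.29
DTHD1	0.13	0.45	0.05	0	0	0.66	1.29
CLC	0.11	0.72	0.02	0	0	0.36	1.21
SNORD20	0.14	0.24	0.01	0.13	0.1	0.5	1.12
CD163	0.15	0.29	0	0.11	0	0.57	1.12
NRG1	0.2	0.25	0.02	0	0	0.63	1.1
SNORD45B	0.12	0.64	0.01	0	0	0.33	1.1
CYP1B1	0.14	0.25	0	0	0	0.66	1.05
KLRC2	0.07	0.51	0	0	0	0.46	1.04
TMEM176A	0.08	0.67	0	0	0	0.24	0.99
SLED1	0.09	0.24	0.02	0.05	0	0.49	0.89
FCGR1A.2	0.23	0	0	0.62	0	0	0.85
SERPINB2	0.08	0.21	0	0	0	0.54	0.83
FCGR1A.1	0.18	0	0	0.62	0	0	0.8
KLRC4	0.13	0.21	0	0	0	0.43	0.77
KLRA1P	0.1	0.07	0	0.08	0	0.51	0.76
MIR21	0.08	0.09	0.01	0	0	0.5	0.68
CES1	0.12	0.05	0.03	0	0	0.47	0.67
KLRC4-KLRK1	0.07	0	0	0.08	0	0.43	0.58
KLRC3	0.07	0.1	0	0	0	0.39	0.56
NRG1.1	0.13	0	0	0	0	0	0.13
FMN1.1	0.07	0	0.01	0	0	0	0.08
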