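gene	tumour_mean	normal_mean	fold_change	raw_p	fdr_p
CCL13	0.71	6.30	0.11	1.70E-23	8.68E-23
CCL19	1.02	7.03	0.14	7.29E-23	3.53E-22
PRKCB	14.65	53.12	0.28	1.52E-41	3.49E-40
TNFRSF13C	1.72	5.88	0.29	1.43E-16	4.88E-16
CD40LG	1.00	3.33	0.30	9.05E-17	3.33E-16
CXCL12	23.04	74.27	0.31	7.44E-49	2.28E-47
PLCG2	16.91	52.18	0.32	1.31E-36	2.00E-35
BTK	5.16	15.34	0.34	4.95E-25	2.87E-24
CCL21	5.84	16.77	0.35	4.21E-16	1.38E-15
BCL2	24.42	62.11	0.39	3.73E-39	6.86E-38
ZAP70	7.77	18.76	0.41	1.51E-21	6.95E-21
LTB	3.10	7.26	0.43	3.88E-13	1.11E-12
BLNK	20.68	47.50	0.44	2.98E-27	2.11E-26
TNFRSF11A	53.68	118.87	0.45	2.30E-21	1.01E-20
LTA	0.61	1.26	0.48	1.13E-04	2.00E-04
LBP	0.15	0.28	0.53	3.39E-02	4.72E-02
LAT	7.72	12.01	0.64	6.19E-10	1.54E-09
CD40	16.05	24.91	0.64	1.97E-08	4.31E-08
IL1R1	57.71	89.40	0.65	9.55E-17	3.38E-16
TNFSF14	6.37	9.76	0.65	3.20E-06	6.01E-06
MAP3K14	33.86	51.73	0.65	1.46E-24	7.90E-24
BIRC3	79.53	120.36	0.66	1.83E-14	5.42E-14
CD14	9.64	14.13	0.68	1.36E-07	2.84E-07
CFLAR	203.49	290.53	0.70	2.89E-29	2.42E-28
RIPK1	49.35	69.68	0.71	1.19E-19	4.57E-19
LY96	0.91	1.25	0.73	9.16E-02	1.15E-01
TNFRSF1A	90.65	118.74	0.76	4.32E-20	1.81E-19
ATM	239.32	312.70	0.77	4.82E-16	1.53E-15
BCL10	42.63	55.30	0.77	4.62E-09	1.06E-08
NFKBIA	58.77	75.03	0.78	1.13E-07	2.41E-07
LCK	8.55	10.61	0.81	2.13E-02	3.06E-02
TIRAP	21.76	26.81	0.81	3.76E-06	6.91E-06
PIAS4	29.27	35.75	0.82	6.64E-07	1.33E-06
BIRC2	81.92	98.12	0.83	6.71E-10	1.63E-09
PRKCQ	7.27	8.69	0.84	3.63E-02	4.99E-02
VCAM1	13.23	15.65	0.85	3.98E-02	5.37E-02
RELB	24.80	28.79	0.86	1.24E-03	1.96E-03
TNFSF13B	4.40	5.11	0.86	9.98E-02	1.24E-01
TRADD	25.11	28.92	0.87	2.47E-03	3.79E-03
TAB2	128.75	146.44	0.88	8.45E-07	1.65E-06
TAB1	29.01	32.68	0.89	1.36E-03	2.13E-03
TRAF1	46.52	51.87	0.90	1.55E-02	2.26E-02
TRIM25	136.97	150.69	0.91	2.32E-04	3.89E-04
ERC1	140.89	154.24	0.91	2.57E-03	3.88E-03
NFKB2	45.18	49.11	0.92	5.89E-02	7.74E-02
NFKB1	77.63	83.98	0.92	7.65E-03	1.14E-02
CARD10	73.25	78.85	0.93	7.35E-02	9.39E-02
PIDD	28.99	31.19	0.93	1.08E-01	1.33E-01
DDX58	45.26	48.56	0.93	1.77E-01	2.06E-01
IKBKB	137.36	145.80	0.94	6.63E-02	8.59E-02
TNF	1.95	2.04	0.96	7.52E-01	7.60E-01
PTGS2	16.66	17.36	0.96	6.99E-01	7.14E-01
TRAF3	34.10	35.38	0.96	3.16E-01	3.54E-01
TNFAIP3	100.76	104.33	0.97	4.13E-01	4.38E-01
TICAM1	23.76	24.47	0.97	5.30E-01	5.54E-01
MYD88	64.07	65.97	0.97	4.14E-01	4.38E-01
IRAK4	39.76	40.57	0.98	5.92E-01	6.11E-01
MALT1	75.70	75.80	1.00	9.69E-01	9.69E-01
TRAF6	38.06	36.78	1.03	3.37E-01	3.74E-01
GADD45B	12.90	12.05	1.07	3.43E-01	3.76E-01
TICAM2	8.19	7.62	1.08	2.73E-01	3.10E-01
CARD11	21.22	19.62	1.08	3.93E-01	4.26E-01
LTBR	126.02	113.31	1.11	1.41E-04	2.44E-04
IKBKG	6.91	6.20	1.11	2.04E-01	2.35E-01
CSNK2B	78.25	70.03	1.12	2.92E-04	4.80E-04
CARD14	12.91	11.54	1.12	1.12E-01	1.35E-01
RELA	82.20	73.32	1.12	5.56E-06	1.00E-05
SYK	111.40	98.12	1.14	1.73E-04	2.94E-04
MAP3K7	72.49	62.09	1.17	9.69E-07	1.86E-06
CHUK	44.48	37.81	1.18	4.50E-04	7.26E-04
TNFSF11	4.36	3.64	1.20	1.30E-01	1.56E-01
XIAP	187.63	156.09	1.20	8.16E-13	2.21E-12
IL1B	22.58	18.76	1.20	2.65E-02	3.74E-02
TAB3	134.33	108.39	1.24	2.64E-09	6.22E-09
BCL2A1	2.01	1.61	1.25	1.59E-01	1.87E-01
CCL4	2.74	2.06	1.33	4.03E-02	5.37E-02
TRAF2	40.20	29.46	1.36	8.02E-13	2.21E-12
PARP1	109.63	79.73	1.37	5.66E-16	1.74E-15
ICAM1	47.42	34.43	1.38	3.56E-07	7.28E-07
TLR4	51.80	37.22	1.39	1.72E-08	3.86E-08
LYN	48.21	33.32	1.45	2.29E-12	5.85E-12
CSNK2A1	138.89	92.92	1.49	5.00E-25	2.87E-24
UBE2I	91.18	61.00	1.49	9.53E-33	1.25E-31
PLCG1	199.37	118.93	1.68	8.50E-31	8.69E-30
TRAF5	185.37	108.42	1.71	3.65E-29	2.80E-28
CSNK2A2	46.72	23.14	2.02	1.14E-30	1.05E-29
CSNK2A1P	1.98	0.91	2.17	1.29E-12	3.39E-12
IRAK1	184.02	82.28	2.24	1.90E-54	8.76E-53
BCL2L1	144.28	64.05	2.25	1.06E-56	9.73E-55
PLAU	54.21	21.51	2.52	6.31E-31	7.25E-30
CXCL2	27.61	10.82	2.55	9.88E-20	3.95E-19
IL8	37.68	7.35	5.12	1.13E-25	7.46E-25
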