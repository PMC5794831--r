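gene	gene_tumour_mean	gene_normal_mean	gene_fc	mirna	mirna_tumour_mean	mirna_normal_mean	mirna_fc	raw_p	fdr_p	seed_match	discordant_beta
BTK	5.16	15.34	0.34	hsa-miR-150-5p	14.90	39.17	0.38	<0.0001	0.0116	1	0
BTK	5.16	15.34	0.34	hsa-miR-203a	12.52	3.70	3.38	<0.0001	0.0116	1	0
BTK	5.16	15.34	0.34	hsa-miR-20b-5p	17.65	3.30	5.35	<0.0001	0.0116	1	0
BTK	5.16	15.34	0.34	hsa-miR-650	4.51	16.60	0.27	<0.0001	0.0116	0	0
CSNK2A2	46.72	23.14	2.02	hsa-miR-20b-5p	17.65	3.30	5.35	<0.0001	0.0271	1	0
CSNK2A2	46.72	23.14	2.02	hsa-miR-6515-5p	1.20	4.41	0.27	<0.0001	0.0271	0	0
CSNK2A2	46.72	23.14	2.02	hsa-miR-92a-3p	121.60	41.18	2.95	<0.0001	0.0271	0	0
TRAF5	185.37	108.42	1.71	hsa-miR-1271-5p	1.28	2.35	0.55	<0.0001	0.0349	1	0
TRAF5	185.37	108.42	1.71	hsa-miR-146a-5p	10.73	6.93	1.55	0.0007	0.0438	0	0
TRAF5	185.37	108.42	1.71	hsa-miR-29a-3p	110.29	51.04	2.16	0.0006	0.0438	1	0
TRAF5	185.37	108.42	1.71	hsa-miR-378g	1.19	2.46	0.48	0.0007	0.0438	0	0
TRAF5	185.37	108.42	1.71	hsa-miR-3923	0.29	1.66	0.18	0.0003	0.0349	0	0
TRAF5	185.37	108.42	1.71	hsa-miR-520d-3p	1.74	2.76	0.63	<0.0001	0.0349	0	0
TRAF5	185.37	108.42	1.71	hsa-miR-5685	1.28	2.78	0.46	0.0003	0.0349	0	0
TRAF5	185.37	108.42	1.71	hsa-miR-92a-3p	121.60	41.18	2.95	0.0003	0.0349	0	0
CD40	16.05	24.91	0.64	hsa-miR-150-5p	14.90	39.17	0.38	<0.0001	0.0136	0	0
CD40	16.05	24.91	0.64	hsa-miR-650	4.51	16.60	0.27	<0.0001	0.0136	0	0
CXCL12	23.04	74.27	0.31	hsa-miR-133b	1.71	6.94	0.25	0.0005	0.037	1	0
CXCL12	23.04	74.27	0.31	hsa-miR-145-5p	132.97	223.14	0.60	0.0003	0.037	0	0
CXCL12	23.04	74.27	0.31	hsa-miR-150-5p	14.90	39.17	0.38	0.0005	0.037	1	0
CXCL12	23.04	74.27	0.31	hsa-miR-193b-3p	9.12	5.42	1.68	<0.0001	0.0326	0	0
CXCL12	23.04	74.27	0.31	hsa-miR-195-5p	3.59	12.18	0.29	0.0002	0.0326	0	0
CXCL12	23.04	74.27	0.31	hsa-miR-497-5p	1.77	7.12	0.25	0.0002	0.0326	0	0
ZAP70	7.77	18.76	0.41	hsa-miR-150-5p	14.90	39.17	0.38	<0.0001	0.0407	0	0
IL1R1	57.71	89.40	0.65	hsa-miR-193b-3p	9.12	5.42	1.68	<0.0001	0.0203	0	0
IL1R1	57.71	89.40	0.65	hsa-miR-214-3p	13.24	6.13	2.16	0.0003	0.0407	1	0
PLAU	54.21	21.51	2.52	hsa-miR-215	49.53	77.27	0.64	0.0002	0.0407	1	0
PLAU	54.21	21.51	2.52	hsa-miR-934	4.36	0.94	4.66	<0.0001	0.0407	0	0
PLCG1	199.37	118.93	1.68	hsa-miR-1246	629.21	412.81	1.52	0.0004	0.0271	1	0
PLCG1	199.37	118.93	1.68	hsa-miR-130b-3p	8.74	4.89	1.79	0.0007	0.0305	0	0
PLCG1	199.37	118.93	1.68	hsa-miR-17-5p	61.04	16.38	3.73	0.0009	0.0305	1	0
PLCG1	199.37	118.93	1.68	hsa-miR-196b-5p	17.89	5.53	3.24	0.0009	0.0305	0	0
PLCG1	199.37	118.93	1.68	hsa-miR-20a-5p	70.78	17.61	4.02	0.0009	0.0305	1	0
PLCG1	199.37	118.93	1.68	hsa-miR-20b-5p	17.65	3.30	5.35	0.0006	0.0305	1	0
PLCG1	199.37	118.93	1.68	hsa-miR-25-3p	30.05	12.78	2.35	0.0005	0.0291	0	0
PLCG1	199.37	118.93	1.68	hsa-miR-375	20.50	54.53	0.38	0.0014	0.0407	1	0
PLCG1	199.37	118.93	1.68	hsa-miR-424-3p	39.81	25.37	1.57	<0.0001	0.0163	0	0
PLCG1	199.37	118.93	1.68	hsa-miR-583	6.61	3.22	2.05	0.0009	0.0305	1	0
PLCG1	199.37	118.93	1.68	hsa-miR-663b	65.50	32.21	2.03	0.0009	0.0305	0	0
PLCG1	199.37	118.93	1.68	hsa-miR-92a-3p	121.60	41.18	2.95	<0.0001	0.0163	0	0
CCL21	5.84	16.77	0.35	hsa-miR-150-5p	14.90	39.17	0.38	<0.0001	0.0203	0	0
CCL21	5.84	16.77	0.35	hsa-miR-195-5p	3.59	12.18	0.29	<0.0001	0.0203	0	0
CCL21	5.84	16.77	0.35	hsa-miR-203a	12.52	3.70	3.38	0.0002	0.0233	0	0
CCL21	5.84	16.77	0.35	hsa-miR-497-5p	1.77	7.12	0.25	0.0002	0.0233	0	0
CCL21	5.84	16.77	0.35	hsa-miR-650	4.51	16.60	0.27	0.0002	0.0233	0	0
TNFRSF11A	53.68	118.87	0.45	hsa-miR-17-5p	61.04	16.38	3.73	0.0021	0.0342	1	0
TNFRSF11A	53.68	118.87	0.45	hsa-miR-193b-3p	9.12	5.42	1.68	<0.0001	0.0063	0	0
TNFRSF11A	53.68	118.87	0.45	hsa-miR-196b-5p	17.89	5.53	3.24	<0.0001	0.0063	1	0
TNFRSF11A	53.68	118.87	0.45	hsa-miR-199a-5p	20.18	9.28	2.17	0.0007	0.0178	1	0
TNFRSF11A	53.68	118.87	0.45	hsa-miR-20b-5p	17.65	3.30	5.35	0.0006	0.0158	1	0
TNFRSF11A	53.68	118.87	0.45	hsa-miR-214-3p	13.24	6.13	2.16	0.0004	0.0125	1	0
TNFRSF11A	53.68	118.87	0.45	hsa-miR-330-3p	2.81	5.59	0.50	0.0015	0.0284	1	0
TNFRSF11A	53.68	118.87	0.45	hsa-miR-361-5p	11.62	6.20	1.87	0.0015	0.0284	0	0
TNFRSF11A	53.68	118.87	0.45	hsa-miR-365a-3p	8.43	4.33	1.94	<0.0001	0.0063	1	0
TNFRSF11A	53.68	118.87	0.45	hsa-miR-375	20.50	54.53	0.38	0.0002	0.0081	1	0
TNFRSF11A	53.68	118.87	0.45	hsa-miR-424-3p	39.81	25.37	1.57	0.0004	0.0125	0	0
TNFRSF11A	53.68	118.87	0.45	hsa-miR-590-5p	1.78	3.04	0.59	0.0029	0.0414	1	1
TNFRSF11A	53.68	118.87	0.45	hsa-miR-663b	65.50	32.21	2.03	0.0005	0.0151	1	0
TNFRSF11A	53.68	118.87	0.45	hsa-miR-92a-3p	121.60	41.18	2.95	0.0002	0.0081	0	0
TNFRSF11A	53.68	118.87	0.45	hsa-miR-934	4.36	0.94	4.66	0.0002	0.0081	1	0
PRKCB	14.65	53.12	0.28	hsa-miR-150-5p	14.90	39.17	0.38	<0.0001	0.0102	1	0
PRKCB	14.65	53.12	0.28	hsa-miR-203a	12.52	3.70	3.38	<0.0001	0.0102	1	0
PRKCB	14.65	53.12	0.28	hsa-miR-650	4.51	16.60	0.27	<0.0001	0.0102	0	0
BCL2L1	144.28	64.05	2.25	hsa-miR-92a-3p	121.60	41.18	2.95	<0.0001	0.0407	0	0
BCL2	24.42	62.11	0.39	hsa-miR-150-5p	14.90	39.17	0.38	<0.0001	0.0203	1	0
BCL2	24.42	62.11	0.39	hsa-miR-195-5p	3.59	12.18	0.29	0.0003	0.0488	1	0
BCL2	24.42	62.11	0.39	hsa-miR-203a	12.52	3.70	3.38	<0.0001	0.0203	1	0
BCL2	24.42	62.11	0.39	hsa-miR-650	4.51	16.60	0.27	<0.0001	0.0203	1	0
CCL13	0.71	6.30	0.11	hsa-miR-221-3p	13.53	4.12	3.28	<0.0001	0.0271	0	0
CCL13	0.71	6.30	0.11	hsa-miR-324-5p	5.20	2.27	2.29	0.0004	0.0452	1	0
CCL13	0.71	6.30	0.11	hsa-miR-34a-5p	25.15	12.32	2.04	0.0004	0.0452	0	0
PLCG2	16.91	52.18	0.32	hsa-miR-150-5p	14.90	39.17	0.38	<0.0001	0.0163	1	0
PLCG2	16.91	52.18	0.32	hsa-miR-195-5p	3.59	12.18	0.29	0.0002	0.0203	1	0
PLCG2	16.91	52.18	0.32	hsa-miR-203a	12.52	3.70	3.38	0.0002	0.0203	1	0
PLCG2	16.91	52.18	0.32	hsa-miR-429	13.33	8.29	1.61	0.0005	0.0407	1	0
PLCG2	16.91	52.18	0.32	hsa-miR-650	4.51	16.60	0.27	<0.0001	0.0163	0	0
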