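gene	mean_carcinoma	mean_normal	fold_change	subset
ANAPC1	75.40	43.01	1.75	overall
ANAPC11	11.96	7.71	1.55	overall
ANAPC13	26.31	17.35	1.52	mss_only
ANAPC7	65.84	43.85	1.50	overall
BUB1	53.35	18.38	2.90	overall
BUB1B	41.59	17.15	2.42	overall
BUB3	94.35	60.85	1.55	overall
CCNA2	40.09	14.62	2.74	overall
CCNB1	32.40	9.25	3.50	overall
CCNB2	21.30	12.39	1.72	overall
CCND1	317.79	122.64	2.59	overall
CCND2	773.45	483.06	1.60	overall
CCNE1	8.70	4.80	1.81	overall
CDC14A	16.20	31.59	0.51	overall
CDC16	90.37	58.88	1.53	overall
CDC20	22.28	10.17	2.19	overall
CDC25A	21.63	10.61	2.04	overall
CDC25B	169.88	60.96	2.79	overall
CDC25C	7.95	3.46	2.30	overall
CDC45	14.50	6.61	2.19	overall
CDC6	32.30	11.33	2.85	overall
CDC7	19.56	10.85	1.80	overall
CDK1	41.36	11.94	3.46	overall
CDK2	45.70	24.96	1.83	overall
CDK4	66.65	26.90	2.48	overall
CDK6	289.15	166.12	1.74	overall
CDK7	23.94	13.17	1.82	overall
CDKN1C	5.45	3.38	1.61	overall
CDKN2B	24.21	74.65	0.32	overall
CHEK1	37.56	15.63	2.40	overall
DBF4	23.05	11.73	1.97	overall
E2F1	27.36	9.14	2.99	overall
E2F3	57.78	34.90	1.66	overall
E2F5	46.80	30.87	1.52	overall
ESPL1	39.52	18.82	2.10	overall
HDAC2	102.64	58.70	1.75	overall
MAD2L1	15.96	4.92	3.24	overall
MAD2L2	9.52	5.51	1.73	overall
MCM2	44.16	17.25	2.56	overall
MCM3	107.53	41.43	2.60	overall
MCM4	115.85	43.65	2.65	overall
MCM5	78.55	50.31	1.56	msi_only
MCM6	55.02	23.15	2.38	overall
MCM7	135.12	64.18	2.11	overall
MDM2	358.47	229.39	1.56	msi_only
MYC	181.11	49.00	3.70	overall
ORC1	13.40	7.68	1.74	overall
ORC5	23.07	15.12	1.53	overall
ORC6	13.15	4.62	2.84	overall
PCNA	37.26	12.83	2.91	overall
PKMYT1	45.18	16.72	2.70	overall
PRKDC	927.46	395.35	2.35	overall
PTTG1	14.78	5.48	2.70	overall
RAD21	257.68	139.20	1.85	overall
RB1	104.85	58.44	1.79	overall
RBL1	53.52	23.32	2.30	overall
SKP2	49.31	24.13	2.04	overall
SMC1A	208.24	133.73	1.56	overall
SMC1B	3.71	6.20	0.60	overall
SMC3	123.45	66.72	1.85	overall
TFDP1	119.20	54.04	2.21	overall
TGFB2	9.23	4.52	2.04	overall
TP53	105.07	59.63	1.76	overall
TTK	28.80	10.97	2.62	overall
WEE1	129.22	85.54	1.51	msi_only
WEE2	1.33	2.11	0.63	overall
YWHAB	389.26	223.04	1.75	overall
YWHAE	214.66	141.14	1.52	overall
YWHAG	241.75	119.30	2.03	overall
YWHAH	102.59	66.00	1.55	overall
YWHAQ	130.47	72.74	1.79	overall
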