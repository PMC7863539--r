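#OTU ID	S0001	S0002	S0003	S0004	S0005	S0006	S0007	S0008	S0009	S0010	S0011	S0012	S0013	S0014	S0015	S0016	S0017	S0018	S0019	S0020	S0021	S0022	S0023	S0024	S0025	S0026	S0027	S0028	S0029	S0030	S0031	S0032	S0033	S0034	S0035	S0036	S0037	S0038	S0039	S0040	S0041	S0042	S0043	S0044	S0045	S0046	S0047	S0048	S0049	S0050	S0051	S0052	S0053	S0054	S0055	S0056	S0057	S0058	S0059	S0060	S0061	S0062	S0063	S0064	S0065	S0066	S0067	S0068	S0069	S0070	S0071	S0072	S0073	S0074	S0075	S0076	S0077	S0078	S0079	S0080	S0081	S0082	S0083	S0084	S0085	S0086	S0087	S0088	S0089	S0090	S0091	S0092	S0093	S0094	S0095	S0096	S0097	S0098	S0099	S0100	S0101	S0102	S0103	S0104	S0105	S0106	S0107	S0108	S0109	S0110	S0111	S0112	S0113	S0114	S0115	S0116	S0117	S0118	S0119	S0120
OTU_0001	60	67	3	3	34	3	1	94	2	66	4	63	5	47	4	2	133	4	3	4	2	6	2	1	3	4	3	2	5	147	31	6	53	5	33	3	2	2	43	4	5	53	3	2	5	4	36	6	42	2	37	41	56	76	49	59	57	5	140	2	7	133	68	4	1	4	52	3	76	91	62	9	77	59	4	61	43	75	5	72	4	67	85	40	5	46	71	83	3	1	64	71	89	4	4	5	49	2	63	3	6	46	2	4	2	3	78	51	2	58	2	49	4	2	3	3	33	4	6	63
OTU_0002	48	100	3	5	68	4	6	79	4	50	4	54	8	71	2	6	54	1	2	3	2	4	3	1	3	6	2	2	3	112	46	4	51	3	56	4	4	5	92	7	3	26	2	2	3	5	52	2	75	4	58	73	75	72	52	82	28	4	73	7	3	65	96	4	3	3	66	2	97	52	57	4	55	61	6	50	58	107	3	52	3	78	50	60	3	45	63	114	4	2	71	58	59	4	4	5	74	2	53	2	4	102	1	3	4	3	47	44	5	58	5	50	5	4	3	5	55	3	3	61
OTU_0003	93	30	30	2	5	4	2	64	4	4	4	68	3	38	7	59	4	39	3	4	3	69	40	4	2	35	4	3	2	3	1	131	1	3	3	2	3	55	6	43	5	4	43	59	46	1	7	109	3	38	4	2	4	4	67	3	92	92	4	3	5	68	105	2	3	93	2	1	4	2	53	4	132	64	5	1	3	1	1	103	4	4	52	40	4	42	8	3	3	1	4	94	3	3	6	4	79	5	4	189	4	92	4	4	5	71	1	2	8	124	61	1	48	1	1	5	3	104	2	2
OTU_0004	4	5	3	45	7	6	91	4	2	31	7	3	2	6	51	2	74	1	53	2	5	3	3	100	62	3	66	50	3	87	3	6	2	57	5	41	38	4	55	2	45	83	2	3	2	73	50	4	52	7	73	33	102	3	3	5	4	9	52	71	4	4	4	4	2	2	3	53	3	48	4	68	4	3	2	105	46	47	49	119	61	5	2	2	60	4	3	4	3	3	132	2	89	5	113	71	3	3	81	4	57	4	4	4	169	3	2	73	3	2	3	65	5	4	2	60	1	3	2	39
OTU_0005	45	3	63	2	50	72	69	48	2	2	25	51	2	61	45	4	1	112	42	4	123	2	3	2	65	4	37	44	39	73	4	49	44	35	4	2	81	127	101	2	94	50	3	3	4	3	70	79	30	57	72	68	66	116	60	3	60	8	2	93	5	2	5	4	90	34	48	2	3	3	60	78	4	113	78	42	39	5	2	4	73	80	2	3	73	48	3	51	2	67	4	65	71	61	59	36	5	105	85	78	65	2	67	52	81	72	3	3	70	81	104	39	2	6	59	6	48	95	2	46
OTU_0006	70	3	2	2	3	43	90	99	2	1	1	4	2	5	3	2	2	64	128	4	36	2	2	2	82	2	5	69	3	6	2	71	12	3	6	1	3	52	1	2	142	59	2	5	2	3	3	2	55	6	60	8	3	58	51	0	32	3	2	109	3	53	5	2	3	4	3	58	3	3	6	63	2	2	44	73	3	3	3	0	46	7	3	3	76	4	2	3	4	68	3	58	2	3	4	50	3	3	5	1	3	5	3	1	3	99	2	3	2	91	95	3	4	3	135	5	39	39	3	56
OTU_0007	9	9	8	76	32	18	16	6	12	54	14	36	31	8	36	39	25	9	6	9	10	16	27	37	11	25	40	8	10	29	12	37	11	9	16	48	44	37	11	7	37	13	17	45	37	32	41	18	43	10	21	25	18	33	31	13	25	20	39	16	13	23	5	37	23	16	24	10	15	11	24	14	2	14	8	11	5	14	63	74	23	15	10	7	7	7	42	8	5	123	28	7	30	17	22	7	3	5	16	91	10	19	2	12	22	38	14	53	7	34	7	15	20	11	30	16	18	8	12	12
OTU_0008	73	105	63	3	4	2	3	104	4	2	2	81	81	35	2	61	5	4	65	81	36	93	2	3	67	3	2	4	72	1	44	3	79	80	2	42	3	3	2	3	6	72	116	25	39	50	5	94	3	72	73	113	6	71	30	112	46	57	2	70	60	2	101	48	85	78	42	3	51	3	67	49	65	78	4	2	5	45	123	66	60	95	2	70	48	39	39	68	8	2	48	127	4	37	2	73	2	4	50	45	65	2	51	2	44	59	3	78	4	60	69	5	90	52	34	4	61	48	4	59
OTU_0009	51	52	11	12	15	37	10	50	9	38	26	30	109	26	28	22	48	76	13	34	8	85	39	82	20	35	66	42	53	69	23	31	30	20	6	19	81	142	14	18	6	34	19	11	23	14	55	38	30	54	40	5	34	40	35	18	31	25	12	113	9	17	65	8	46	22	22	7	17	38	21	66	29	28	26	38	70	52	50	84	21	27	105	20	47	35	118	87	33	43	3	27	46	159	31	44	30	11	30	44	35	47	28	20	58	11	48	31	4	19	70	6	79	78	65	27	19	9	27	24
OTU_0010	53	104	48	5	5	61	131	5	4	8	4	4	1	4	132	2	4	92	43	92	2	93	68	8	5	2	69	3	4	2	4	4	3	2	40	4	3	4	3	7	4	1	3	6	67	1	3	3	4	5	4	5	43	1	2	4	3	3	46	59	94	3	38	1	4	4	4	105	4	4	3	3	3	2	1	4	2	1	3	1	4	38	124	52	4	6	30	71	1	3	5	55	30	1	3	189	2	3	64	64	2	39	4	3	1	2	93	2	7	4	59	79	35	1	68	103	92	42	109	40
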