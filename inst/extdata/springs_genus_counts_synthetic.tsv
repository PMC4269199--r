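site	genus01	genus02	genus03	genus04	genus05	genus06	genus07	genus08	genus09	genus11	genus12	genus13	genus14	genus15	genus16	genus18	genus19	genus20	genus21	genus22	genus23	genus24	genus25	genus26	genus27	genus28	genus30	genus31	genus32	genus33	genus34	genus35	genus36	genus37	genus38	genus39	genus40	genus41	genus42	genus44	genus45	genus46	genus48	genus49	genus50	genus51	genus52	genus53	genus54	genus55	genus56	genus57	genus58	genus59	genus60	genus61	genus62	genus63	genus64	genus65	genus66	genus67	genus68	genus69	genus70	genus71	genus73	genus74	genus75	genus76	genus77	genus78	genus79
Eiland	23	336	0	19	0	0	18	0	0	23	0	0	0	0	0	0	33	0	0	0	0	0	0	15	0	0	0	1	0	0	0	0	0	0	0	0	0	27	0	0	0	0	0	0	0	12	0	0	0	0	0	0	16	0	32	0	83	0	6	0	0	0	0	0	0	0	0	0	0	0	0	76	0
Mphephu	21	0	0	0	330	0	0	0	0	0	8	5	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	96	0	0	0	0	0	0	0	0	0	0	26	0	19	0	0	23	0	1	0	0	0	0	0	0	0	0	44	0	0	0	11	0	16	0	0	69	0	0	52	0	0	0
Sagole	16	0	0	0	0	0	0	0	0	0	0	0	360	0	14	0	0	16	0	12	0	0	0	0	15	0	0	0	4	0	0	0	0	0	27	4	0	0	0	0	0	0	69	0	0	0	0	10	0	0	0	0	0	0	0	0	0	0	0	80	6	0	0	0	0	161	0	0	0	0	0	0	0
Siloam	15	0	0	0	0	0	0	0	0	0	0	0	0	0	0	232	0	0	0	0	4	85	6	0	0	0	0	0	0	15	0	32	12	0	0	0	0	0	22	4	0	0	0	0	0	0	0	0	0	88	0	1	0	0	0	0	0	0	0	0	0	0	0	0	5	0	0	0	0	0	0	0	47
Souting	1	0	66	0	0	0	0	7	0	0	0	0	0	1	0	0	0	0	4	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	3	0	0	0	2	0	0	0	0	0	0	0	0	0	0	19	0	0	0	0	0	0	0	0	0	0	0	2	27	0	0	0	0
Tshipise	2	0	0	0	0	62	0	0	9	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	3	17	0	0	0	0	0	0	5	0	0	2	0	0	0	0	0	0	0	0	0	0	0	0	0	6	0	0	7	0	0	0	0	0	0	0	0	3	0	0	0	0	0	0	0	4	0	0
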