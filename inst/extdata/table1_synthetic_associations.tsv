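rsid	genes	p_value	odds_ratio	source_id
rs7000001	IKZF1	1e-07	1.2	GCST800001
rs7000001	IKZF1	1e-08	1.3	GCST800002
rs7000001	IKZF1	1e-09	1.4	GCST800003
rs7000001	IKZF1	1e-10	1.5	GCST800004
rs7000001	IKZF1	1e-06	1.6	GCST800005
rs7000002	IKZF1	1e-07	1.7	GCST800006
rs7000002	IKZF1	1e-08	1.8	GCST800007
rs7000002	IKZF1	1e-09	1.9	GCST800008
rs7000002	IKZF1	1e-10	 2	GCST800009
rs7000003	IKZF1	1e-06	2.1	GCST800010
rs7000003	IKZF1	1e-07	2.2	GCST800011
rs7000003	IKZF1	1e-08	2.3	GCST800012
rs7000003	IKZF1	1e-09	1.1	GCST800013
rs7000004	ARID5B	1e-10	1.2	GCST800014
rs7000004	ARID5B	1e-06	1.3	GCST800015
rs7000004	ARID5B	1e-07	1.4	GCST800016
rs7000005	ARID5B	1e-08	1.5	GCST800017
rs7000005	ARID5B	1e-09	1.6	GCST800018
rs7000005	ARID5B	1e-10	1.7	GCST800019
rs7000006	ARID5B	1e-06	1.8	GCST800020
rs7000006	ARID5B	1e-07	1.9	GCST800021
rs7000006	ARID5B	1e-08	 2	GCST800022
rs7000007	ARID5B	1e-09	2.1	GCST800023
rs7000007	ARID5B	1e-10	2.2	GCST800024
rs7000007	ARID5B	1e-06	2.3	GCST800025
rs7000008	GATA3	1e-07	1.1	GCST800026
rs7000008	GATA3	1e-08	1.2	GCST800027
rs7000008	GATA3	1e-09	1.3	GCST800028
rs7000008	GATA3	1e-10	1.4	GCST800029
rs7000008	GATA3	1e-06	1.5	GCST800030
rs7000008	GATA3	1e-07	1.6	GCST800031
rs7000008	GATA3	1e-08	1.7	GCST800032
rs7000008	GATA3	1e-09	1.8	GCST800033
rs7000008	GATA3	1e-10	1.9	GCST800034
rs7000008	GATA3	1e-06	 2	GCST800035
rs7000008	GATA3	1e-07	2.1	GCST800036
rs7000009	SLC7A8, CEBPE	1e-08	2.2	GCST800037
rs7000009	SLC7A8, CEBPE	1e-09	2.3	GCST800038
rs7000009	SLC7A8, CEBPE	1e-10	1.1	GCST800039
rs7000009	SLC7A8, CEBPE	1e-06	1.2	GCST800040
rs7000010	SLC7A8, CEBPE	1e-07	1.3	GCST800041
rs7000010	SLC7A8, CEBPE	1e-08	1.4	GCST800042
rs7000010	SLC7A8, CEBPE	1e-09	1.5	GCST800043
rs7000011	CDKN2A	1e-10	1.6	GCST800044
rs7000011	CDKN2A	1e-06	1.7	GCST800045
rs7000012	CDKN2A	1e-07	1.8	GCST800046
rs7000013	CDKN2A	1e-08	1.9	GCST800047
rs7000014	LHPP	1e-09	 2	GCST800048
rs7000014	LHPP	1e-10	2.1	GCST800049
rs7000015	LHPP	1e-06	2.2	GCST800050
rs7000016	LHPP	1e-07	2.3	GCST800051
rs7000017	PIP4K2A	1e-08	1.1	GCST800052
rs7000017	PIP4K2A	1e-09	1.2	GCST800053
rs7000018	PIP4K2A	1e-10	1.3	GCST800054
rs7000019	PIP4K2A	1e-06	1.4	GCST800055
rs7000020	CCDC26	1e-07	1.5	GCST800056
rs7000021	CCDC26	1e-08	1.6	GCST800057
rs7000022	CCDC26	1e-09	1.7	GCST800058
rs7000023	ELK3	1e-10	1.8	GCST800059
rs7000023	ELK3	1e-06	1.9	GCST800060
rs7000023	ELK3	1e-07	 2	GCST800061
rs7000024	GPATCH2L	1e-08	2.1	GCST800062
rs7000024	GPATCH2L	1e-09	2.2	GCST800063
rs7000024	GPATCH2L	1e-10	2.3	GCST800064
rs7000025	OR5AL1, OR5AL2P	1e-06	1.1	GCST800065
rs7000025	OR5AL1, OR5AL2P	1e-07	1.2	GCST800066
rs7000025	OR5AL1, OR5AL2P	1e-08	1.3	GCST800067
rs7000026	PDE4B	1e-09	1.4	GCST800068
rs7000027	PDE4B	1e-10	1.5	GCST800069
rs7000028	PDE4B	1e-06	1.6	GCST800070
rs7000029	RNU6-366P, CPSF2	1e-07	1.7	GCST800071
rs7000029	RNU6-366P, CPSF2	1e-08	1.8	GCST800072
rs7000029	RNU6-366P, CPSF2	1e-09	1.9	GCST800073
rs7000030	TP63	1e-10	 2	GCST800074
rs7000030	TP63	1e-06	2.1	GCST800075
rs7000030	TP63	1e-07	2.2	GCST800076
rs7000031	CSGALNACT1, INTS10	1e-08	2.3	GCST800077
rs7000031	CSGALNACT1, INTS10	1e-09	1.1	GCST800078
rs7000032	DDC, FIGNL1	1e-10	1.2	GCST800079
rs7000032	DDC, FIGNL1	1e-06	1.3	GCST800080
rs7000033	ERG	1e-07	1.4	GCST800081
rs7000033	ERG	1e-08	1.5	GCST800082
rs7000034	AGBL1	1e-09	1.6	GCST800083
rs7000034	AGBL1	1e-10	1.7	GCST800084
rs7000035	PTPRJ	1e-06	1.8	GCST800085
rs7000035	PTPRJ	1e-07	1.9	GCST800086
rs7000036	RN7SL361P, BCL11A	1e-08	 2	GCST800087
rs7000036	RN7SL361P, BCL11A	1e-09	2.1	GCST800088
rs7000037	RNU6-1091P, IKZF1	1e-10	2.2	GCST800089
rs7000038	RNU6-1091P, IKZF1	1e-06	2.3	GCST800090
rs7000039	RPL6P5	1e-07	1.1	GCST800091
rs7000039	RPL6P5	1e-08	1.2	GCST800092
rs7000040	SGL01	1e-09	1.3	GCST800093
rs7000041	SGL02	1e-10	1.4	GCST800094
rs7000042	SGL03	1e-06	1.5	GCST800095
rs7000043	SGL04	1e-07	1.6	GCST800096
rs7000044	SGL05	1e-08	1.7	GCST800097
rs7000045	SGL06	1e-09	1.8	GCST800098
rs7000046	SGL07	1e-10	1.9	GCST800099
rs7000047	SGL08	1e-06	 2	GCST800100
rs7000048	SGL09	1e-07	2.1	GCST800101
rs7000049	SGL10	1e-08	2.2	GCST800102
rs7000050	SGL11	1e-09	2.3	GCST800103
rs7000051	SGL12	1e-10	1.1	GCST800104
rs7000052	SGL13	1e-06	1.2	GCST800105
rs7000053	SGL14	1e-07	1.3	GCST800106
rs7000054	SGL15	1e-08	1.4	GCST800107
rs7000055	SGL16	1e-09	1.5	GCST800108
rs7000056	SGL17	1e-10	1.6	GCST800109
rs7000057	SGL18	1e-06	1.7	GCST800110
rs7000058	SGL19	1e-07	1.8	GCST800111
rs7000059	SGL20	1e-08	1.9	GCST800112
rs7000060	SGL21	1e-09	 2	GCST800113
rs7000061	SGL22	1e-10	2.1	GCST800114
rs7000062	SGL23	1e-06	2.2	GCST800115
rs7000063	SGL24	1e-07	2.3	GCST800116
rs7000064	SGL25	1e-08	1.1	GCST800117
rs7000065	SGL26	1e-09	1.2	GCST800118
rs7000066	SGL27	1e-10	1.3	GCST800119
rs7000067	SGL28	1e-06	1.4	GCST800120
rs7000068	SGL29	1e-07	1.5	GCST800121
rs7000069	SGL30	1e-08	1.6	GCST800122
rs7000070	SGL31	1e-09	1.7	GCST800123
rs7000071	SGL32	1e-10	1.8	GCST800124
rs7000072	SGL33	1e-06	1.9	GCST800125
rs7000073	not known	1e-07	 2	GCST800126
rs7000073	not known	1e-08	2.1	GCST800127
rs7000074	not known	1e-09	2.2	GCST800128
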