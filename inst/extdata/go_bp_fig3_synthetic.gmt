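GO:0050817	coagulation	F2	F5	F9	F11	FGA	FGB	VWF	KLKB1	THBD	PROC	ADAMTS13	ST3GAL4	EXTG001	EXTG002	EXTG003	EXTG004	EXTG005	EXTG006	EXTG007	EXTG008
GO:0042060	wound healing	PLEK	PLCG2	THBD	F5	F2	VWF	FGA	FGB	EXTG009	EXTG010	EXTG011	EXTG012	EXTG013	EXTG014
GO:1903034	regulation of response to wounding	SH2B3	KLKB1	F9	F11	PROC	F5	F2	EXTG015	EXTG016	EXTG017	EXTG018
GO:0006954	inflammatory response	IL6R	IL1RN	EXTG019	EXTG020	EXTG021	EXTG022	EXTG023	EXTG024	EXTG025	EXTG026
GO:0006811	monoatomic ion transport	ATP1B1	SLC44A2	EXTG027	EXTG028	EXTG029	EXTG030	EXTG031	EXTG032	EXTG033	EXTG034	EXTG035	EXTG036
GO:0007596	platelet activation	GP6	F8	EXTG037	EXTG038	EXTG039	EXTG040	EXTG041	EXTG042	EXTG043	EXTG044
GO:0030168	protein processing	PROCR	FGG	EXTG045	EXTG046	EXTG047	EXTG048	EXTG049	EXTG050	EXTG051	EXTG052
GO:0016337	cell-cell adhesion	TSPAN15	NME7	EXTG053	EXTG054	EXTG055	EXTG056	EXTG057	EXTG058	EXTG059	EXTG060
GO:0008015	blood circulation	SERPINC1	PROS1	ABO	EXTG061	EXTG062	EXTG063	EXTG064	EXTG065	EXTG066	EXTG067	EXTG068
GO:9000001	background process 1	EXTG069	EXTG070	EXTG071	EXTG072	EXTG073	EXTG074	EXTG075	EXTG076	EXTG077
GO:9000002	background process 2	EXTG078	EXTG079	EXTG080	EXTG081	EXTG082	EXTG083	EXTG084	EXTG085	EXTG086
GO:9000003	background process 3	EXTG087	EXTG088	EXTG089	EXTG090	EXTG091	EXTG092	EXTG093	EXTG094	EXTG095
GO:9000004	background process 4	EXTG096	EXTG097	EXTG098	EXTG099	EXTG100	EXTG101	EXTG102	EXTG103	EXTG104
GO:9000005	background process 5	EXTG105	EXTG106	EXTG107	EXTG108	EXTG109	EXTG110	EXTG111	EXTG112	EXTG113
GO:9000006	background process 6	EXTG114	EXTG115	EXTG116	EXTG117	EXTG118	EXTG119	EXTG120	EXTG121	EXTG122
GO:9000007	background process 7	EXTG123	EXTG124	EXTG125	EXTG126	EXTG127	EXTG128	EXTG129	EXTG130	EXTG131
GO:9000008	background process 8	EXTG132	EXTG133	EXTG134	EXTG135	EXTG136	EXTG137	EXTG138	EXTG139	EXTG140
GO:9000009	background process 9	EXTG141	EXTG142	EXTG143	EXTG144	EXTG145	EXTG146	EXTG147	EXTG148	EXTG149
GO:9000010	background process 10	EXTG150	EXTG151	EXTG152	EXTG153	EXTG154	EXTG155	EXTG156	EXTG157	EXTG158
GO:9000011	background process 11	EXTG159	EXTG160	EXTG161	EXTG162	EXTG163	EXTG164	EXTG165	EXTG166	EXTG167
GO:9000012	background process 12	EXTG168	EXTG169	EXTG170	EXTG171	EXTG172	EXTG173	EXTG174	EXTG175	EXTG176
GO:9000013	background process 13	EXTG177	EXTG178	EXTG179	EXTG180	EXTG181	EXTG182	EXTG183	EXTG184	EXTG185
GO:9000014	background process 14	EXTG186	EXTG187	EXTG188	EXTG189	EXTG190	EXTG191	EXTG192	EXTG193	EXTG194
GO:9000015	background process 15	EXTG195	EXTG196	EXTG197	EXTG198	EXTG199	EXTG200	EXTG201	EXTG202	EXTG203
GO:9000016	background process 16	EXTG204	EXTG205	EXTG206	EXTG207	EXTG208	EXTG209	EXTG210	EXTG211	EXTG212
GO:9000017	background process 17	EXTG213	EXTG214	EXTG215	EXTG216	EXTG217	EXTG218	EXTG219	EXTG220	EXTG221
GO:9000018	background process 18	EXTG222	EXTG223	EXTG224	EXTG225	EXTG226	EXTG227	EXTG228	EXTG229	EXTG230
GO:9000019	background process 19	EXTG231	EXTG232	EXTG233	EXTG234	EXTG235	EXTG236	EXTG237	EXTG238	EXTG239
GO:9000020	background process 20	EXTG240	EXTG241	EXTG242	EXTG243	EXTG244	EXTG245	EXTG246	EXTG247	EXTG248
GO:9000021	background process 21	EXTG249	EXTG250	EXTG251	EXTG252	EXTG253	EXTG254	EXTG255	EXTG256	EXTG257
GO:9000022	background process 22	EXTG258	EXTG259	EXTG260	EXTG261	EXTG262	EXTG263	EXTG264	EXTG265	EXTG266
GO:9000023	background process 23	EXTG267	EXTG268	EXTG269	EXTG270
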