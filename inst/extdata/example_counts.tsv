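sgRNA	gene	lineA_r1	lineA_r2	lineB_r1	lineB_r2
sg001	GENE01	211	222	195	203
sg002	GENE01	206	200	197	197
sg003	GENE02	183	191	218	187
sg004	GENE02	180	193	205	205
sg005	GENE03	206	184	203	209
sg006	GENE03	190	196	190	207
sg007	GENE04	215	219	197	215
sg008	GENE04	193	192	209	214
sg009	GENE05	201	205	199	201
sg010	GENE05	185	217	189	203
sg011	GENE06	184	193	213	201
sg012	GENE06	197	209	205	181
sg013	GENE07	198	226	205	193
sg014	GENE07	196	202	202	192
sg015	GENE08	174	185	211	173
sg016	GENE08	162	220	181	217
sg017	GENE09	202	183	210	176
sg018	GENE09	207	194	216	189
sg019	GENE10	200	183	215	186
sg020	GENE10	219	215	205	214
sg021	GENE11	188	184	200	203
sg022	GENE11	220	197	197	208
sg023	GENE12	258	249	255	272
sg024	GENE12	219	259	265	260
sg025	GENE13	273	226	257	255
sg026	GENE13	231	280	259	239
sg027	GENE14	14	23	19	19
sg028	GENE14	10	15	12	15
sg029	GENE15	14	18	18	16
sg030	GENE15	12	8	14	12
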