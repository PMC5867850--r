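accession	organism	total_ctag	total_gatc	ctag_per_kb	gatc_per_kb	gatc_over_ctag	dam_match	group
NC_013967.1	Haloferax volcanii DS2	671	1851	0.24	0.65	2.8	FALSE	halobacteria
NZ_CP007551.1	Haloferax mediterranei ATCC 33500	1130	1472	0.38	0.50	1.3	FALSE	halobacteria
NZ_CP011947.1	Haloferax gibbonsii strain ARA6	556	1510	0.19	0.51	2.7	FALSE	halobacteria
NC_017941.2	Haloferax mediterranei ATCC 33500	1142	1500	0.39	0.51	1.3	FALSE	halobacteria
NC_023013.1	Haloarcula hispanica N601 chr.1	1497	7523	0.50	2.50	5.0	FALSE	halobacteria
NC_023010.2	Haloarcula hispanica N601 chr.2	340	1675	0.94	4.61	4.9	FALSE	halobacteria
NZ_CP010529.1	Haloarcula sp. CBA1115	1849	9333	0.54	2.73	5.0	FALSE	halobacteria
NC_006396.1	Haloarcula marismortui ATCC 43049 chr.I	1816	6564	0.58	2.10	3.6	FALSE	halobacteria
NC_006397.1	Haloarcula marismortui ATCC 43049 chr.II	274	1011	0.95	3.51	3.7	FALSE	halobacteria
NC_015948.1	Haloarcula hispanica ATCC 33960 chr.I	1493	7462	0.50	2.49	5.0	FALSE	halobacteria
NC_015943.1	Haloarcula hispanica ATCC 33960 chr.II	479	2210	0.98	4.52	4.6	FALSE	halobacteria
NZ_LN831302.1	Halobacterium hubeiense strain JI20-1	795	1820	0.32	0.72	2.3	FALSE	halobacteria
NZ_CP007060.1	Halobacterium sp. DL1	1168	4634	0.41	1.63	4.0	FALSE	halobacteria
NC_002607.1	Halobacterium sp. NRC-1	551	11047	0.27	5.48	20.0	FALSE	halobacteria
NC_010364.1	Halobacterium salinarum R1	537	10991	0.27	5.49	20.5	FALSE	halobacteria
NC_012029.1	Halorubrum lacusprofundi ATCC 49239 chr.1	756	25016	0.28	9.15	33.1	TRUE	halobacteria
NC_012028.1	Halorubrum lacusprofundi ATCC 49239 chr.2	389	3306	0.74	6.29	8.5	TRUE	halobacteria
NC_007426.1	Natronomonas pharaonis DSM 2160	1016	1839	0.39	0.71	1.8	FALSE	halobacteria
NC_008212.1	Haloquadratum walsbyi DSM 16790	2290	14449	0.73	4.61	6.3	FALSE	halobacteria
NC_017459.1	Haloquadratum walsbyi C23	2281	14681	0.72	4.66	6.4	FALSE	halobacteria
NC_014729.1	Halogeometricum borinquense DSM 11551	1085	8407	0.38	2.98	7.7	FALSE	halobacteria
CP024845.1	Halophilic archaeon True-ADL	1786	23542	0.54	7.07	13.2	FALSE	halobacteria
NC_021921.1	Halorhabdus tiamatea SARL4B	892	27010	0.32	9.59	30.3	TRUE	halobacteria
NC_013158.1	Halorhabdus utahensis DSM 12940	964	32101	0.31	10.30	33.3	FALSE	halobacteria
NC_013202.1	Halomicrobium mukohataei DSM 12286	918	27978	0.30	8.99	30.5	FALSE	halobacteria
NC_013743.1	Haloterrigena turkmenica DSM 5511	1347	37472	0.35	9.64	27.8	FALSE	halobacteria
NC_013922.1	Natrialba magadii ATCC 43099	1592	25139	0.42	6.70	15.8	FALSE	halobacteria
NC_014297.1	Halalkalicoccus jeotgali B3	1106	29489	0.39	10.50	26.7	FALSE	halobacteria
NC_015666.1	Halopiger xanaduensis SH-6	1090	33560	0.30	9.15	30.8	FALSE	halobacteria
NC_018224.1	Natrinema sp. J7-2	1393	33801	0.38	9.14	24.3	FALSE	halobacteria
NC_019792.1	Natronobacterium gregoryi SP2	2330	31628	0.62	8.35	13.6	FALSE	halobacteria
NC_019962.1	Natrinema pellirubrum DSM 15624	1384	36667	0.37	9.67	26.5	FALSE	halobacteria
NC_019964.1	Halovivax ruber XH-70	1256	30664	0.39	9.51	24.4	FALSE	halobacteria
NC_019974.1	Natronococcus occultus SP4	1534	42563	0.38	10.61	27.7	FALSE	halobacteria
NC_020388.1	Natronomonas moolapensis 8.8.11	1088	23003	0.37	7.90	21.1	FALSE	halobacteria
NC_021313.1	Salinarchaeum sp. Harcht-Bsk1	948	33056	0.29	10.15	34.9	FALSE	halobacteria
NZ_AP017558.1	Halopenitus persicus DNA CBA1233	695	31995	0.23	10.78	46.0	TRUE	halobacteria
NZ_AP017569.1	Halorubrum trapanicum DNA CBA1232	426	19948	0.15	7.03	46.8	TRUE	halobacteria
NZ_CP007055.1	Halostagnicola larsenii XH-48	1094	24861	0.39	8.91	22.7	FALSE	halobacteria
NZ_CP008874.1	Halanaeroarchaeum sulfurireducens HSR2	596	15696	0.29	7.53	26.3	FALSE	halobacteria
NZ_CP011564.1	Halanaeroarchaeum sulfurireducens M27-SA2	637	16067	0.30	7.55	25.2	FALSE	halobacteria
NZ_CP016070.1	Halodesulfurarchaeum formicicum HTSR1	639	18453	0.32	9.36	28.9	FALSE	halobacteria
NZ_CP016804.1	Halodesulfurarchaeum formicicum HSR6	696	19038	0.33	9.13	27.4	FALSE	halobacteria
NZ_CP019067.1	Halorientalis sp. IM1011	1046	25987	0.31	7.68	24.8	TRUE	halobacteria
NZ_CP019285.1	Halobiforma lacisalsi AJ5	1235	40138	0.30	9.64	32.5	FALSE	halobacteria
NZ_CP019327.1	Haloterrigena daqingensis JX313	1124	25935	0.33	7.63	23.1	FALSE	halobacteria
NZ_CP019893.1	Natrialbaceae archaeon JW/NM-HA 15	1177	35113	0.30	8.93	29.8	TRUE	halobacteria
NC_000913.3	Escherichia coli str K-12 substr MG1655	885	19124	0.19	4.12	21.6	TRUE	comparison
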