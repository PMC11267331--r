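Protein IDs	Gene names	Reverse	Potential contaminant	Only identified by site	GOCC names	LFQ intensity term_UT_1	LFQ intensity term_UT_2	LFQ intensity term_UT_3	LFQ intensity term_UT_4	LFQ intensity term_TiO2_1	LFQ intensity term_TiO2_2	LFQ intensity term_TiO2_3	LFQ intensity term_TiO2_4
CON__P001	CONT1		+		extracellular space	1048580	1048580	1048580	1048580	1048580	1048580	1048580	1048580
REV__P002		+				1048580	1048580	1048580	1048580	1048580	1048580	1048580	1048580
P003	SITE1			+	extracellular exosome	1048580	1048580	1048580	1048580	1048580	1048580	1048580	1048580
P004	PRES1				extracellular exosome	1048580	0	0	0	0	0	0	0
P005	PRES2				extracellular space	0	0	0	0	2097150	0	0	0
P006	NUC1				nucleus	2097150	2247670	1956710	2097150	2409000	2097150	1825680	2247670
P007	CYT1				cytoplasm	4194300	4495340	3913420	4194300	4495340	4194300	3913420	4342220
P008	UPP1				extracellular exosome	1048580	1123840	978356	1085550	8388610	7826850	8990690	8684430
P009	DWN1				extracellular space	4194300	4495340	3913420	4342220	1048580	1123840	978356	1012860
P010	NUL1				secretory granule	2097150	2247670	1956710	2171110	2171110	2025720	2247670	1956710
P011	NUL2				extracellular vesicle	8388610	8990690	7826850	8684430	8505710	8866910	8102860	8388610
P012	NUL3				secretory granule lumen	524288	561918	489178	542777	539028	546552	517070	527935
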