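marker_id	chrom	start	end	repeat_unit	reference_length
MSI001	chr1	16332867	16332891	CA	12
MSI002	chr1	53614422	53614444	A	22
MSI003	chr1	106160927	106160937	A	10
MSI004	chr1	127795043	127795069	A	26
MSI005	chr1	148872893	148872917	A	24
MSI006	chr2	21217559	21217584	A	25
MSI007	chr2	56643535	56643549	T	14
MSI008	chr2	63291665	63291691	A	26
MSI009	chr2	85015437	85015455	T	18
MSI010	chr2	191168876	191168903	T	27
MSI011	chr3	74062758	74062773	T	15
MSI012	chr3	77802639	77802665	A	26
MSI013	chr3	80213864	80213898	AG	17
MSI014	chr3	80895960	80895980	AG	10
MSI015	chr3	84225414	84225432	A	18
MSI016	chr4	56702181	56702196	T	15
MSI017	chr4	76729969	76729994	A	25
MSI018	chr4	110105788	110105813	T	25
MSI019	chr4	128064466	128064492	T	26
MSI020	chr4	195911020	195911035	A	15
MSI021	chr5	18451871	18451896	T	25
MSI022	chr5	35070993	35071013	T	20
MSI023	chr5	49603598	49603646	CA	24
MSI024	chr5	124473564	124473579	A	15
MSI025	chr5	149856089	149856110	T	21
MSI026	chr6	37290850	37290875	A	25
MSI027	chr6	66808961	66808981	CA	10
MSI028	chr6	149313130	149313148	A	18
MSI029	chr6	161612957	161612982	A	25
MSI030	chr6	185241364	185241412	AG	24
MSI031	chr7	42698104	42698156	AG	26
MSI032	chr7	55939044	55939062	A	18
MSI033	chr7	95143245	95143272	A	27
MSI034	chr7	101336182	101336208	A	26
MSI035	chr7	137632626	137632644	A	18
MSI036	chr8	41226542	41226563	A	21
MSI037	chr8	65402000	65402021	A	21
MSI038	chr8	164154852	164154869	T	17
MSI039	chr8	176951377	176951388	T	11
MSI040	chr8	179637954	179637998	CA	22
MSI041	chr9	3331907	3331931	T	24
MSI042	chr9	71814488	71814509	T	21
MSI043	chr9	101088033	101088059	CA	13
MSI044	chr9	161562196	161562216	A	20
MSI045	chr9	174053613	174053639	A	26
MSI046	chr10	2027730	2027744	T	14
MSI047	chr10	2360781	2360796	A	15
MSI048	chr10	21221492	21221516	CA	12
MSI049	chr10	36561095	36561145	CA	25
MSI050	chr10	62598168	62598191	A	23
MSI051	chr11	35595405	35595445	AG	20
MSI052	chr11	76909996	76910028	CA	16
MSI053	chr11	95355422	95355436	A	14
MSI054	chr11	155763048	155763068	CA	10
MSI055	chr11	174884638	174884662	A	24
MSI056	chr12	73776114	73776130	T	16
MSI057	chr12	80938528	80938541	A	13
MSI058	chr12	117646490	117646509	T	19
MSI059	chr12	119256097	119256113	A	16
MSI060	chr12	127127660	127127685	T	25
MSI061	chr13	72996835	72996865	AG	15
MSI062	chr13	101451499	101451513	A	14
MSI063	chr13	143779728	143779740	A	12
MSI064	chr13	145096310	145096327	A	17
MSI065	chr13	198911879	198911909	CA	15
MSI066	chr14	29560872	29560894	T	22
MSI067	chr14	40221399	40221441	AG	21
MSI068	chr14	81324831	81324841	A	10
MSI069	chr14	111659860	111659890	AG	15
MSI070	chr14	148107446	148107457	A	11
MSI071	chr15	36479041	36479071	AG	15
MSI072	chr15	58078760	58078800	AG	20
MSI073	chr15	77341123	77341143	CA	10
MSI074	chr15	121052666	121052691	T	25
MSI075	chr15	147339954	147339971	A	17
MSI076	chr16	29789056	29789079	T	23
MSI077	chr16	34444072	34444098	A	26
MSI078	chr16	121524425	121524440	A	15
MSI079	chr16	142795387	142795403	T	16
MSI080	chr16	146397142	146397162	T	20
MSI081	chr17	3041727	3041771	CA	22
MSI082	chr17	20239336	20239348	T	12
MSI083	chr17	40984416	40984466	AG	25
MSI084	chr17	102444526	102444549	A	23
MSI085	chr17	136374050	136374080	CA	15
MSI086	chr18	27719129	27719156	A	27
MSI087	chr18	37587218	37587228	T	10
MSI088	chr18	66316377	66316407	CA	15
MSI089	chr18	74990518	74990530	A	12
MSI090	chr18	183079056	183079074	T	18
MSI091	chr19	22386974	22387006	AG	16
MSI092	chr19	50229271	50229285	T	14
MSI093	chr19	80201498	80201516	A	18
MSI094	chr19	98244722	98244768	AG	23
MSI095	chr19	186599166	186599184	T	18
MSI096	chr20	22251029	22251081	CA	26
MSI097	chr20	42413091	42413102	T	11
MSI098	chr20	63542108	63542127	T	19
MSI099	chr20	65909128	65909144	A	16
MSI100	chr20	187703334	187703354	T	20
MSI101	chr21	20404865	20404913	AG	24
MSI102	chr21	92242741	92242761	A	20
MSI103	chr21	162636057	162636078	A	21
MSI104	chr21	174806264	174806287	A	23
MSI105	chr21	193099270	193099294	AG	12
MSI106	chr22	44179739	44179789	AG	25
MSI107	chr22	59175646	59175667	A	21
MSI108	chr22	62974418	62974434	A	16
MSI109	chr22	68761700	68761734	AG	17
MSI110	chr22	84520608	84520634	CA	13
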