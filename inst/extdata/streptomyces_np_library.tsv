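name	formula	mz	adduct	rt_min	mw	source	reference	note
1-Cyclohexenecarboxylic acid	C7H10O2	127.0755	[M+H]+	2.19	126.0683	Str. collinus TU 1892	lit-39	
Okilactomycin D	C23H32O4	371.2221	[M-H]-	4.94	372.2294	Str. scabrisporus F-117187	lit-40	
Viridenomycin	C34H37NO6	554.2564	[M-H]-	9.42	555.2637	Str. viridochromogenes T-24146 and Str. gannmycicus	lit-41,42	antitumour; antibacterial
MKN-003B	C12H20O3	213.1483	[M+H]+	2.66	212.14099	Streptoverticillium luteoverticillatum 11014 and Streptomyces sp. M02750	lit-43,44	antitumour; antifungal
Atramycin A	C25H24O9	467.1361	[M-H]-	1.40	468.1434	Str. atratus BY90	lit-45	antitumour
Antibiotic BE 12406A	C25H24O9	467.1361	[M-H]-	1.40	468.1434	Streptomyces sp. BA12406	lit-46,47	cytotoxic
Landomycin I (8-D-Olivosyl-landomycin)	C25H24O9	467.13614	[M-H]-	1.40	468.1434	Str. cyanogenus S-136	lit-48	cytotoxic
Bohemamine B	C14H20N2O3	265.1546	[M+H]+	2.85	264.1473	Streptomyces sp. CNQ-583	lit-49	
Bohemamine C	C14H20N2O3	265.1546	[M+H]+	2.85	264.1473	Streptomyces sp. CNQ-583	lit-49	
Furaquinocin C	C22H26O5	369.1704	[M-H]-	2.49	370.1777	Streptomyces sp. KO-3988	lit-50	
Elaiomycin D	C13H24N2O4	273.1817	[M+H]+	2.52	272.1744	Streptomyces sp. HKI0708	lit-51	
Sulfurmycin B	C43H51NO16	836.3112	[M-H]-	6.24	837.3184	Str. galilaeus OB-111	lit-52,53	
Violapyrone A	C12H18O3	211.1324	[M+H]+	4.47	210.1251	Str. violascens YIM 100525	lit-54	antibacterial
Elaiomycin L	C12H24N2O4	261.1807	[M+H]+	2.13	260.1734	Streptomyces sp. Tü 6399	lit-55	antibacterial
Feigrisolide B	C11H20O4	217.1428	[M+H]+	2.87	216.1355	Str. griseus GT 051022	lit-56	antifungal; antiviral
Dienomycin C	C16H21NO	244.1695	[M+H]+	1.73	243.1623	Streptomyces sp. MC67-C1	lit-57	
Antibiotic X-1092	C11H20N2O4	245.1494	[M+H]+	1.81	244.1422	Streptomyces sp. X-1092	lit-58	
Tirandamycin D	C22H27NO6	400.1764	[M-H]-	6.76	401.1837	Streptomyces sp. 307-9	lit-59	antibacterial
Tirandalydigin	C22H27NO6	400.1764	[M-H]-	6.76	401.1837	Str. tirandis subsp. umidus AB1006A-9	lit-60	antibacterial
Antibiotic FL 120B	C22H18N2O7	421.1038	[M-H]-	5.59	422.1111	Str. chattanoogensis subsp. taitungensis IY2-13	lit-61	antibacterial
Antibiotic S-583-B	C59H78N2O20	1135.5238	[M+H]+	0.82	1134.5165	Str. purpurascens S-583	lit-62	
Phoslactomycin C	C30H48NO10P	614.3094	[M+H]+	7.44	613.3021	Str. nigrescens SC-273	lit-63	antifungal
Clavamycin F	C15H24N4O7	371.1562	[M-H]-	6.53	372.1635	Str. hygroscopicus NRRL 15879	lit-64,65	antifungal
Phenamide	C14H20N2O3	265.1546	[M+H]+	2.93	264.1471	Str. albospinus A19301	lit-66	
Oxytetracycline	C22H24N2O9	459.14032	[M-H]-	5.45	460.1476	Str. rimosus	lit-67,68	antibacterial
Filipin III	C35H58O11	655.4051	[M+H]+	2.24	654.3978	Str. filipinensis	lit-69,70	antifungal
Filipin IV	C35H58O11	655.4051	[M+H]+	2.24	654.3978	Str. filipinensis	lit-69,70	antifungal
Novamethymycin	C25H43NO8	486.3055	[M+H]+	3.98	485.2982	Str. venezuelae	lit-71	antibacterial
Deoxyvalidamine	C7H15NO3	162.1125	[M+H]+	2.82	161.1052	Str. hygroscopicus subsp. Limoneus	lit-72	glucosidase inhibitor
L-1, 4-Cyclohexadiene-1-alanine	C9H13NO2	168.1023	[M+H]+	3.64	167.095	Str. diastatochromogenes var. sakaii	lit-73	
PI 201	C17H28O3	281.2106	[M+H]+	2.00	280.2033	Streptomyces sp. A7498	lit-74	
Diolmycin A1	C18H19NO3	298.1434	[M+H]+	4.43	297.1361	Streptomyces sp. WK-2955	lit-75	
Benzastatine D	C19H28N2O3	331.2018	[M-H]-	1.80	332.2091	Str. nitrosporeus 30643	lit-76	
Benzastatine E	C19H28N2O3	331.2018	[M-H]-	1.80	332.2091	Str. nitrosporeus 30643	lit-77	
Neocarazostatin B	C22H27NO3	352.1921	[M-H]-	6.82	353.1994	Streptomyces sp. GP38	lit-78	
Histargin	C14H25N7O4	354.1902	[M-H]-	6.93	355.1975	Str. roseoviridis MF118-A5	lit-79	
Aestivophoenin B	C36H40N2O7	613.2894	[M+H]+	0.47	612.2821	Str. purpeofuscus 2887-SVS2	lit-80	
Delactonmycin	C22H36O4	365.2696	[M+H]+	1.86	364.2624	Streptomyces sp. A92-308902	lit-81	
Flaviogeranin	C22H26O5	369.1704	[M+H]+	2.49	370.1777	Streptomyces sp. RAC226	lit-82	
Antibiotic EM 2487	C32H57N5O16P2	828.3187	[M-H]-	4.87	829.3259	Streptomyces sp. Mer-2487	lit-83	
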