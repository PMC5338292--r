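row_id	recipient_species	recipient_lineage	accession	start	end	length	genes	bs	donor_lineage	donor_sister_flag	flank5_code	flank3_code	host_parasite_flag	source_ref
1	Amborella trichopoda	basal Magnoliophyta; Amborellales	KF754801	124144	127171	3028	psbC; psbD	NA	Santalales	FALSE	no1	no3	TRUE	ref1
2	Amborella trichopoda	basal Magnoliophyta; Amborellales	KF754803	3077656	3078925	1270	rbcL	NA	Santalales	FALSE	yes5	no3	TRUE	ref1
3	Amborella trichopoda	basal Magnoliophyta; Amborellales	KF754803	474251	476207	1957	psaA	NA	rosids; fabids; Oxalidales	FALSE	no3	no5	FALSE	ref1
4	Amborella trichopoda	basal Magnoliophyta; Amborellales	KF754799	57856	61814	3959	rps7; rps12; trnV; rrnS	NA	rosids; fabids; Fagales; Fagaceae	FALSE	yes5	no3	FALSE	ref1
5	Asclepias syriaca	asterids; lamiids; Gentianales	NC_022796	29093	29432	340	ndhB-1	100	rosids; fabids; Fabales	FALSE	yes4	no1	FALSE	this_study
6	Asclepias syriaca	asterids; lamiids; Gentianales	NC_022797	40124	42206	2083	ndhB-1; rps7; rps12	100	rosids; fabids; Fabales	FALSE	no1	no2	FALSE	this_study
7	Asclepias syriaca	asterids; lamiids; Gentianales	NC_022798	310073	311353	1281	non-coding region	100	rosids; fabids; Fabales	FALSE	no3	yes5	FALSE	this_study
8	Asclepias syriaca	asterids; lamiids; Gentianales	NC_022796	497713	497990	278	ndhD	100	rosids; malvids; Malvales; Malvaceae	FALSE	no1	no2	FALSE	this_study
9	Cucurbita pepo	rosids; fabids; Cucurbitales	NC_014050	252522	253546	1025	cemA; petA	100	asterids; lamiids; Lamiales; Orobanchaceae	FALSE	no1	yes4	TRUE	this_study
10	Cucurbita pepo	rosids; fabids; Cucurbitales	NC_014050	848217	849548	1332	rps7	93	rosids; fabids; Malpighiales; Euphorbiaceae; Acalyphoideae	FALSE	no2	no1	FALSE	this_study
11	Erythranthe guttata	asterids; lamiids; Lamiales	NC_018041	469539	469886	348	rps7	90	rosids; fabids; Fabales; Fabaceae	FALSE	no3	no3	FALSE	this_study
12	Geranium brycei	rosids; malvids; Geraniales	KP974317	47781	49416	1636	rbcL	NA	asterids; lamiids; Solanales; Convolvulaceae; Cuscuta	FALSE	no3	no3	TRUE	ref2
13	Geranium brycei	rosids; malvids; Geraniales	KP974313	55290	56417	1128	psaA	NA	asterids; lamiids; Solanales; Convolvulaceae; Cuscuta	FALSE	no1	yes5	TRUE	ref2
14	Geranium brycei	rosids; malvids; Geraniales	KP974311	98551	100870	2320	psaB; rps14	NA	asterids; lamiids; Solanales; Convolvulaceae; Cuscuta	FALSE	no3	yes5	TRUE	ref2
15	Geranium brycei	rosids; malvids; Geraniales	KP974317	42601	44151	1551	atpB; atpE	NA	asterids; lamiids; Solanales; Convolvulaceae; Cuscuta	FALSE	no3	no3	TRUE	ref2
16	Geranium brycei	rosids; malvids; Geraniales	KP974311	343448	347166	3719	rpl2 intron; rpoB 3'; rpoC1 exon 1; ndhJ	NA	rosids; fabids; Malpighiales; Euphorbiaceae; Acalyphoideae	FALSE	no3	yes6	FALSE	ref2
17	Geranium brycei	rosids; malvids; Geraniales	KP974311	87980	89010	1031	petB	NA	rosids; fabids; Malpighiales; Euphorbiaceae; Acalyphoideae	FALSE	yes6	yes6	FALSE	ref2
18	Geranium brycei	rosids; malvids; Geraniales	KP974317	19534	20704	1171	psbD	NA	rosids; fabids; Malpighiales; Euphorbiaceae; Acalyphoideae	FALSE	no1	no3	FALSE	ref2
19	Geranium brycei	rosids; malvids; Geraniales	KP974312	105427	106239	813	matK	NA	asterids; lamiids; Gentianales; Rubiaceae; Rubioideae	FALSE	no3	yes6	FALSE	ref2
20	Geranium maderense	rosids; malvids; Geraniales	NC_027000	454189	454564	376	trnA; trnG	98	asterids; lamiids; Lamiales	FALSE	no3	yes4	FALSE	this_study
21	Glycine max	rosids; fabids; Fabales	NC_020455	230204	230895	692	rbcL	NA	asterids; lamiids; Gentianales; Apocynaceae	FALSE	yes4	yes4	FALSE	ref3
22	Gossypium harknessii	rosids; malvids; Malvales	NC_027406	365728	365950	223	psbD	82	rosids; fabids; Malpighiales; Euphorbiaceae	FALSE	yes4	no3	FALSE	this_study
23	Helianthus annuus	asterids; campanulids; Asterales	NC_023337	107850	108495	646	infA; rps8; rps11	98	rosids; Saxifragales; Penthoraceae	FALSE	no5	yes5	FALSE	this_study
24	Hyoscyamus niger	asterids; lamiids; Solanales	NC_026515	351599	353572	1974	rps12	98	rosids; Rosales; Cannabaceae	FALSE	yes4	yes4	FALSE	this_study
25	Hyoscyamus niger	asterids; lamiids; Solanales	NC_026515	354959	355152	194	non-coding region	99	rosids; Rosales; Cannabaceae	TRUE	yes4	yes4	FALSE	this_study
26	Hyoscyamus niger	asterids; lamiids; Solanales	NC_026515	355156	356418	1263	petB	100	rosids; Rosales; Cannabaceae; Cannabis	TRUE	yes4	yes4	FALSE	this_study
27	Lophophytum mirabile	Santalales	KU992322 to KU992380	NA	NA	245	rpl2	100	rosids; fabids; Fabales; Mimosoideae; Acacia ligulata	TRUE	yes5	yes4	TRUE	ref4
28	Lophophytum mirabile	Santalales	KU992322 to KU992380	NA	NA	726	rrn23	80	rosids; fabids; Fabales; Mimosoideae; Acacia ligulata	TRUE	no3	yes5	TRUE	ref4
29	Lophophytum mirabile	Santalales	KU992322 to KU992380	NA	NA	638	psbA	100	rosids; fabids; Fabales; Mimosoideae; Acacia ligulata	TRUE	yes4	yes5	TRUE	ref4
30	Lophophytum mirabile	Santalales	KU992322 to KU992380	NA	NA	520	rpl16	72	rosids; fabids; Fabales; Mimosoideae	FALSE	no3	no3	TRUE	ref4
31	Lophophytum mirabile	Santalales	KU992322 to KU992380	NA	NA	673	petG; trnW	76	rosids; fabids; Fabales; Mimosoideae; Acacia ligulata	TRUE	yes5	yes4	TRUE	ref4
32	Lophophytum mirabile	Santalales	KU992322 to KU992380	NA	NA	269	rbcL	99	rosids; fabids; Fabales; Fabaceae	FALSE	no3	no5	TRUE	ref4
33	Lophophytum mirabile	Santalales	KU992322 to KU992380	NA	NA	771	rpl2	90	rosids; fabids; Fabales; Fabaceae	FALSE	yes4	no1	TRUE	ref4
34	Lotus japonicus	rosids; fabids; Fabales	NC_016743	307253	308275	1023	rbcL	NA	asterids; lamiids; Solanales; Convolvulaceae; Cuscuta	FALSE	yes4	no3	TRUE	ref3
35	Phoenyx dactylifera	Liliopsida; Arecaceae	NC_016740	179688	180534	847	trnI; trnA	NA	rosids; fabids; Fagales; Fagaceae	FALSE	no3	no3	FALSE	ref3
36	Rhazya stricta	asterids; lamiids; Gentianales	NC_024293	236269	237891	1623	trnI; ycf2	87	asterids; lamiids; Lamiales; Oleaceae; Oleeae; Hesperelaea	TRUE	no3	yes4	FALSE	this_study
37	Salvia miltiorrhiza	asterids; lamiids; Lamiales	NC_023209	209571	209920	350	psbA	100	rosids; fabids; Fabales; Fabaceae	FALSE	yes4	yes5	FALSE	this_study
38	Sapria himalayana	rosids; fabids; Malpighiales	NA	NA	NA	1737	psbC; psbD	NA	rosids; Vitales; Tetrastigma	TRUE	no1	yes5	TRUE	ref5
39	Sapria himalayana	rosids; fabids; Malpighiales	NA	NA	NA	395	psbA	NA	rosids; Vitales; Tetrastigma	TRUE	no1	no3	TRUE	ref5
40	Sapria himalayana	rosids; fabids; Malpighiales	NA	NA	NA	504	ndhB	NA	rosids; Vitales; Tetrastigma	FALSE	yes4	no3	TRUE	ref5
41	Sapria himalayana	rosids; fabids; Malpighiales	NA	NA	NA	477	atpB	NA	rosids; Vitales; Tetrastigma	TRUE	no1	yes5	TRUE	ref5
42	Sapria himalayana	rosids; fabids; Malpighiales	NA	NA	NA	3703	rpoC1; rpoC2	NA	rosids; Vitales; Tetrastigma	FALSE	yes4	yes4	TRUE	ref5
43	Sapria himalayana	rosids; fabids; Malpighiales	NA	NA	NA	2595	rps12	NA	rosids; Vitales	FALSE	NA	yes5	TRUE	ref5
44	Sapria himalayana	rosids; fabids; Malpighiales	NA	NA	NA	436	rbcL	NA	rosids; Vitales	FALSE	no3	no3	TRUE	ref5
45	Sapria himalayana	rosids; fabids; Malpighiales	NA	NA	NA	360	psaB	NA	rosids; Vitales; Tetrastigma	TRUE	no1	no3	TRUE	ref5
46	Sapria himalayana	rosids; fabids; Malpighiales	NA	NA	NA	457	atpA	NA	asterids; campanulids; Apiales; Daucus	FALSE	no3	no1	TRUE	ref5
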