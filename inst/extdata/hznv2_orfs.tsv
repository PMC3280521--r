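orf_id	strand	start	end	length_nt	length_aa	predicted_function	species	evalue	signature	hznv1_orf
Hz2V001	R	5630	2298	3333	1111				TAF, H3	1
Hz2V002	F	7183	13047	5865	1955					154
Hz2V003	F	13677	14378	702	234					151
Hz2V004	R	16594	15830	765	255					150
Hz2V005	F	17366	17803	438	146					148
Hz2V006	F	17779	18063	285	95					
Hz2V007	R	21403	19241	2163	721	Carboxylesterase	Drosophila pseudoobscura	3 x 10-21	Coesterase	145
Hz2V008	R	23425	22421	1005	335	Integrase	Monodon baculovirus	1 x 10-29	INT_REC_C	144
Hz2V009	R	23621	23430	192	64					143
Hz2V010	R	26839	24425	2415	805					141
Hz2V011	R	29383	26969	2415	805					140
Hz2V012	F	30140	30700	561	187	Inhibitor of apoptosis protein	Trichoplusia ni SNPV	7 x 10-25	BIR	138
Hz2V013	F	31151	32494	1344	448					137
Hz2V014	F	33735	35312	1578	526					
Hz2V015	F	36168	36713	546	182	Inhibitor of apoptosis protein	Adoxophyes orana GV	120	BIR	135
Hz2V016	F	36879	38201	1323	441					134
Hz2V017	R	39326	39138	189	63					133
Hz2V018	R	43848	40441	3408	1136	DNA polymerase	Oryctes rhinoceros NV	1 x 10-25	POLBc	131
Hz2V019	F	44032	44442	411	137					130
Hz2V020	R	46083	45655	429	143					129
Hz2V021	R	49108	47033	2076	692					128
Hz2V022	F	49210	49731	522	174					
Hz2V023	F	49772	51307	1536	512	Membrane transporter	Ades aegyptii	1 x 10-135	MFS_1	126
Hz2V024	F	51575	52000	426	142					125
Hz2V025	F	52066	52392	327	109					124
Hz2V026	F	52998	54137	1140	380	Per-os infectivity factor 2	Gryllus bimaculatus NV	5 x 10-37	Baculo_44	123
Hz2V027	F	54224	56023	1800	600					122
Hz2V028	R	57374	56376	999	333	Very late expression factor 1	Monodon baculovirus	1 x 10-8		121
Hz2V029	R	60667	58199	2469	823	DNA repair related ATPase	Gryllus bimaculatus NV	3 x 10-4	SbcC	119
Hz2V030	F	60709	61674	966	322					118
Hz2V031	R	63063	62671	393	131					117
Hz2V032	F	63532	64803	1272	424					115
Hz2V033	R	68086	66803	1284	428					112
Hz2V034	F	68319	69323	1005	335	Guanosine monophosphate kinase	Monodon baculovirus	4 x 10-5	GMPK	111
Hz2V035	F	69749	70621	873	291	Thymidylate synthase	Bombyx mori	4 x 10-131	Thymidylat_synt	109
Hz2V036	R	75567	71800	3768	1256					107
Hz2V037	F	76171	77190	1020	340					106
Hz2V038	R	83046	78304	4743	1581	Helicase	Culex nigripalpus NPV	2.8	Pox_D5	104
Hz2V039	F	83048	85156	2109	703	19kDa protein	Gryllus bimaculatus NV	9 x 10-9	Baculo_19	103
Hz2V040	R	86584	85862	723	241	Late expression factor 5	Spodoptera exigua NPV	6 x 10-3	Baculo_LEF5	101
Hz2V041	F	86863	87756	894	298					100
Hz2V042	F	87845	88594	750	250					99
Hz2V043	R	92546	89928	2619	873	Late expression factor 4	Gryllus bimaculatus NV	3 x 10-18		98
Hz2V044	R	94003	92963	1041	347					97
Hz2V045	F	94110	94313	204	68					
Hz2V046	F	94306	95775	1470	490					96
Hz2V047	F	96009	98822	2814	938	Ribonuclease reductase	Spodoptera litura NPV	0	Ribonuc_red_lgC	95
Hz2V048	R	99573	99214	360	120					94
Hz2V049	F	99730	100473	744	248					93
Hz2V050	F	100458	101336	879	293					
Hz2V051	R	105733	101939	3795	1265	Late expression factor 8	Gryllus bimaculatus NV	1 x 10-12	RNA_pol_Rpb2_6	90
Hz2V052	F	105870	106712	843	281					89
Hz2V053	F	107253	107894	642	214	Per-os infectivity factor 3	Gryllus bimaculatus NV	2 x 10-10		88
Hz2V054	R	108853	108413	441	147					87
Hz2V055	F	109110	109391	282	94					85
Hz2V056	F	109953	111365	1413	471					83
Hz2V057	F	113318	113530	213	71					
Hz2V058	R	115909	115496	414	138					81
Hz2V059	F	116202	116963	762	254	p34 late protein	Helicoverpa zea NV-1 d	8 x 10-147		79
Hz2V060	F	117224	117595	372	124					78
Hz2V061	F	117803	118570	768	256					77
Hz2V062	R	120105	118786	1320	440	Odv-e56 structural protein	Gryllus bimaculatus NV	2 x 10-9		76
Hz2V063	R	124121	120513	3609	1203	Late expression factor 9	Monodon baculovirus	1 x 10-60		75
Hz2V064	F	124357	124818	462	154					74
Hz2V065	F	124932	125930	999	333	Ribonuclease reductase	Xenopus tropicalis	5 x 10-128	Ribonuc_red_sm	73
Hz2V066	R	127832	126510	1323	441	Serine hydroxymethyltransferase	Bombyx mori	0	SHMT	72
Hz2V067	F	128939	129760	822	274	Deoxynucleotide kinase	Drosophila melanogaster	1 x 10-38	dNK	71
Hz2V068	F	129972	132338	2367	789	Matrix metalloprotease	Acyrthosiphon pisum	3 x 10-69	ZnMc_MMP, HX	70
Hz2V069	R	134585	133536	1050	350	dUTPase	Culex quinquefasciatus	2 x 10-38	dUTPase	69
Hz2V070	R	137400	135430	1971	657	DNA excision repair enzyme	Musca domestica SGHV	2 x 10-7	XPG	68
Hz2V071	R	138863	137478	1386	462					67
Hz2V072	R	139354	139019	336	112					66
Hz2V073	F	139721	140869	1149	383	p51 late protein	Helicoverpa zea NV-1 d	0		64
Hz2V074	F	141013	141564	552	184					63
Hz2V075	F	141693	145637	3945	1315					62
Hz2V076	R	149608	146981	2628	876					60
Hz2V077	F	149749	150978	1230	410					59
Hz2V078	R	153629	151443	2187	729					58
Hz2V079	R	154524	154090	435	145					
Hz2V080	R	155191	154481	711	237					
Hz2V081	F	155556	155936	381	127					56
Hz2V082	F	156150	157853	1704	568	Per-os infectivity factor 1	Gryllus bimaculatus NV	6 x 10-23	DUF686	55
Hz2V083	F	158080	158742	663	221					54
Hz2V084	R	163557	159694	3864	1288					52
Hz2V085	F	163804	165702	1899	633					51
Hz2V086	R	166298	165954	345	115					
Hz2V087	F	167038	168003	966	322					49
Hz2V088	R	170084	168429	1656	552					47
Hz2V089	F	170456	172948	2493	831	vp91 capsid protein	Gryllus bimaculatus NV	4 x 10-14		46
Hz2V090	F	173649	176570	2922	974					
Hz2V091	F	177136	178524	1389	463					
Hz2V092	F	178677	180614	1938	646					
Hz2V093	F	182846	185689	2844	948	Methyltransferase	Helicoverpa zea NPV	8 x 10-28	FtsJ	37
Hz2V094	F	187572	193430	5859	1953	DNA ligase	Apis mellifera	4 x 10-86	DNA_ligase_A_M	36
Hz2V095	R	194548	193964	585	195					34
Hz2V096	F	194663	195130	468	156	Ac81	Gryllus bimaculatus NV	6 x 10-12	DUF845	33
Hz2V097	F	195232	195630	399	133					32
Hz2V098	F	195699	199133	3435	1145					31
Hz2V099	R	200794	199931	864	288	Esterase/lipase	Psychromonas ingrahamii	0.16	Aes	30
Hz2V100	F	200858	201796	939	313					29
Hz2V101	R	203059	201992	1068	356					28
Hz2V102	R	203298	203092	207	69					
Hz2V103	F	209783	209980	198	66					
Hz2V104	R	216330	215599	732	244					13
Hz2V105	R	217543	216668	876	292					12
Hz2V106	R	219936	217846	2091	697	p74 envelope protein	Gryllius bimaculus NV	5 x 10-57	Baculo_p74	11
Hz2V107	F	220177	220464	288	96					
Hz2V108	R	221727	220951	777	259	38kDa protein	Monodon baculovirus	3 x 10-15	DUF705	10
Hz2V109	R	222547	221819	729	243					9
Hz2V110	F	222677	223438	762	254	Protein kinase	Trichomonas vaginalis	5 x 10-18	S_TKc	8
Hz2V111	F	223656	224297	642	214	Dihydrofolate reductase	Heliothis virescens	1 x 10-45	DHFR	7
Hz2V112	F	226341	229232	2892	964					4
Hz2V113	F	229783	231468	1686	562					3
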