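sample_id	group	stage	replicate	env_axis	TN	NH4	NO3	AP	AK	TS	pH	moisture	OM	density	unit_weight
CT0_S1_R1	0	1	1	-0.075	0.868052290181967	2.61626660141238	10.8587518639395	27.1770915875702	139.706470601991	0.140140942779018	7.68136435346183	28.1398679023016	18.4936090196717	1.48374366343504	14.8283404199517
CT0_S1_R2	0	1	2	-0.075	0.928473404010227	4.27335836938634	9.81890960304948	28.790627780066	142.524477756519	0.115098934135488	7.60674996481931	27.6912473850889	15.0677331933423	1.46003499447032	14.5241530705686
CT0_S1_R3	0	1	3	-0.075	0.714683542621282	4.43944441735448	10.0162360296689	27.6099768880251	148.382500994352	0.139414034221438	7.55429280765274	25.679961885577	18.8799867424406	1.42612032152908	14.6338421205077
CT0_S2_R1	0	2	1	0.075	1.34832982062599	5.9672923358597	11.5571666796148	33.8588145710613	167.527312257792	0.21074883888605	7.38037297480144	29.2287173639779	24.6317909960179	1.36233603934293	14.0437966248275
CT0_S2_R2	0	2	2	0.075	1.27384717044928	5.13559536443791	10.2037007019911	31.1432161648802	149.667358744438	0.288072360398619	7.42897483196992	32.1344734874272	25.9481561035586	1.28589748888542	13.8365420202474
CT0_S2_R3	0	2	3	0.075	1.27006173961394	5.38895703968456	10.0241547411265	31.9156582301252	156.741387596852	0.243645827147696	7.40193139126294	32.5287502322635	24.6834410311184	1.33806144993677	13.6597392264643
CT50_S1_R1	50	1	1	0.425	1.93961498842131	11.1073552862114	9.54493367753291	39.7781109870494	191.797314119633	0.423661627804841	6.77455599696828	45.3189766797109	34.9264723021914	1.09694397114756	10.9670652273389
CT50_S1_R2	50	1	2	0.425	1.87536897550745	11.2360490069295	9.86392122501885	39.9133535699593	191.407892212492	0.423739465209815	6.93668963197496	50.9706316998335	38.0186340642504	1.02057429270521	11.0086632422442
CT50_S1_R3	50	1	3	0.425	1.90496003408587	11.4367734444416	10.202344475639	40.9069689034494	192.734480396862	0.456589431460716	6.71686048465477	46.1918257032892	34.4684045489441	1.02807872559244	11.6662827647234
CT50_S2_R1	50	2	1	0.575	2.34033710510161	13.7551236057794	9.50106949371322	46.6373357155713	198.708248275286	0.56039483450925	6.59389843113265	55.4478185816459	45.639333505306	1.02765685308683	10.3523356863916
CT50_S2_R2	50	2	2	0.575	2.29445336141903	14.4440367811964	11.3682254141912	46.8030508278713	198.797176399871	0.593626110586754	6.68041342588308	51.5179728079752	44.0457465216009	0.91594028714459	9.97731221711269
CT50_S2_R3	50	2	3	0.575	2.16152957581359	15.1341015455778	9.43972473942431	45.4004672568682	206.163206431675	0.502154055087399	6.75159496361102	51.5332368976544	46.5227494728284	0.921770015764203	10.4709886004698
CT100_S1_R1	100	1	1	0.925	2.78727459196182	19.8980132571828	10.2164622498563	52.8740320129503	246.768683343428	0.678945819522534	6.1555653246331	67.5852401290275	59.734934559362	0.732630308194152	8.42900495707565
CT100_S1_R2	100	1	2	0.925	2.72305112696189	18.8270380195919	9.71716142645432	52.1485108783051	240.949339478433	0.76257516091519	6.16102037437276	66.4162767863705	56.8077847064568	0.689609977044445	8.59201614371848
CT100_S1_R3	100	1	3	0.925	2.82721798530394	18.0503269420917	10.696854910818	53.1922213560857	233.40991124428	0.749877402878522	6.0932693063946	66.4737877040535	56.3737640413858	0.676855383932525	8.72137273729945
CT100_S2_R1	100	2	1	1.075	3.123951172956	21.0085279889666	10.5416962337592	57.587740150167	257.464279728391	0.845840190393468	5.73945874936319	72.9867682897687	65.680903592811	0.543905775019809	6.95554737054105
CT100_S2_R2	100	2	2	1.075	2.99258567191277	22.0242683992252	9.3843107396964	56.2962263121357	253.981231969155	0.836988625122063	5.86677222305036	72.7291858348273	58.0343460280874	0.483543054411148	7.82544360770433
CT100_S2_R3	100	2	3	1.075	3.32544243110669	22.7127360477055	9.95733708860238	57.3144171407417	258.234704260268	0.874825078013405	5.85733123648272	75.5528104430532	62.5515176146934	0.629082980159347	7.46122854626319
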