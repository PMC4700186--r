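gene_id	accession	chromosome	start	end	copy_number	intron_number	amino_acids	pI	MW_kDa	decamer
ZmVQ1	GRMZM2G417835	chr1	14384994	14386612	1	1	189	6.79	20.5117	FRALVQELTG
ZmVQ2	GRMZM2G420357	chr1	19475469	19476633	1	0	245	11.14	25.3897	FRDVVQKLTG
ZmVQ3	GRMZM2G318652	chr1	51894857	51895988	1	0	168	9	17.1789	FRAIVQELTG
ZmVQ4	GRMZM2G128644	chr1	52252488	52253871	1	0	201	7.85	20.5732	FRAMVQRVTG
ZmVQ5	GRMZM2G174650	chr1	98163516	98164868	1	0	269	9.68	27.8542	FMSIVQKLTG
ZmVQ6	GRMZM2G158976	chr1	102948793	102950569	1	0	308	11.72	32.5699	FRDIVQQLTA
ZmVQ7	GRMZM2G421934	chr1	108121650	108121832	1	0	61	9.98	6.536	FADTVQRLTG
ZmVQ8	GRMZM2G420630	chr1	108265783	108266565	1	0	145	7.13	15.3235	FRAVVQQLTG
ZmVQ9	GRMZM2G059064	chr1	179720212	179720868	1	2	127	10.78	13.1287	FRDLVQRLTG
ZmVQ10	GRMZM2G118172	chr1	256796579	256797344	1	0	118	10.54	0.01054	FRELVQRLTG
ZmVQ11	GRMZM2G174210	chr1	286181853	286182602	1	0	171	10.63	17.524	FMTVVQRLTG
ZmVQ12	AC206638.3_FG007	chr2	3085080	3085499	1	0	139	6.9	14.8377	FRKVVQRLTG
ZmVQ13	GRMZM2G023921	chr2	5836317	5837195	1	0	195	9.41	20.6742	FRALVQKLTG
ZmVQ14	GRMZM2G369742	chr2	55036620	55038324	1	0	315	9.56	32.6818	FMALVQRLTG
ZmVQ15	GRMZM2G147443	chr2	148868258	148868925	2	0	192	10.22	20.2358	FRRMVHQATG
ZmVQ16	GRMZM2G101409	chr2	217684825	217685795	1	0	202	6.09	20.8743	FRLMVQQITG
ZmVQ17	GRMZM2G354123	chr2	234191571	234192146	1	0	191	11.27	19.7975	FKALVQRLTG
ZmVQ18	GRMZM2G055404	chr3	4722232	4723313	1	0	215	9.72	21.6507	FKQVVQILTG
ZmVQ19	GRMZM2G378442	chr3	45046974	45048075	1	0	249	8.38	24.8667	FQRMVQEITG
ZmVQ20	GRMZM2G314520	chr3	197382762	197384196	1	1	251	9.92	26.1273	FKQVVQMLTG
ZmVQ21	AC194056.3_FG008	chr3	213548727	213548999	1	0	90	6.72	9.5955	FKSIVQRLTG
ZmVQ22	GRMZM2G066599	chr4	76383639	76385196	1	0	346	7.79	35.352	FRAMVQEFTG
ZmVQ23	GRMZM2G322950	chr4	180649502	180650342	1	0	199	9.23	20.8331	FRAMVQELTG
ZmVQ24	GRMZM2G153597	chr4	225854653	225855069	1	0	131	8.62	14.2658	FKDLVQRLTG
ZmVQ25	GRMZM2G010333	chr4	235719536	235720135	1	0	191	8.71	19.2745	FRAMVQQLTG
ZmVQ26	GRMZM2G124290	chr5	4619463	4620282	1	0	182	10.63	18.4941	FMTVVQRLTG
ZmVQ27	GRMZM2G129140	chr5	13723734	13724402	1	0	121	9.81	12.0265	FRELVQRLTG
ZmVQ28	GRMZM2G325208	chr5	36298809	36299476	2	0	192	10.22	20.2358	FRRMVHQATG
ZmVQ29	AC207043.3_FG002	chr5	86012514	86014204	1	0	234	10.08	23.6371	FRAMVQQFTG
ZmVQ30	GRMZM2G346837	chr5	170825684	170827402	1	0	287	8.89	30.3402	FMALVQRLTG
ZmVQ31	GRMZM2G061941	chr5	208198242	208199181	1	0	208	8.77	20.9701	FRAMVQELTG
ZmVQ32	GRMZM2G003669	chr6	702374	703544	1	0	324	9.62	33.6895	FMSVVQRLTG
ZmVQ33	GRMZM2G420715	chr6	93586452	93587633	1	0	240	7.21	24.4229	FRAMVQQFTG
ZmVQ34	GRMZM2G082118	chr6	98257582	98258396	1	0	189	5.32	20.6533	FRDLVQRLTG
ZmVQ35	GRMZM2G099691	chr6	102547587	102548371	1	0	215	11.09	22.191	FLPLVQRLTG
ZmVQ36	GRMZM2G174558	chr6	160717320	160718691	1	0	217	10.13	22.9341	FKQVVQRLTG
ZmVQ37	GRMZM5G814101	chr6	165559690	165560640	1	1	109	8.79	12.0866	FKSVVQRFTG
ZmVQ38	GRMZM2G355499	chr7	6739000	6742999	1	1	210	10.52	21.6087	FKALVQRLTG
ZmVQ39	GRMZM2G083285	chr7	28262041	28262919	1	0	291	9.31	31.7463	FKAAVQRLTG
ZmVQ40	GRMZM2G126413	chr7	100523345	100525002	1	0	416	6.29	40.8146	FRAMVQEFTG
ZmVQ41	GRMZM2G316033	chr7	166745558	166746285	1	0	228	6.66	23.4719	FRAMVQEFTG
ZmVQ42	GRMZM2G151909	chr8	22843785	22844855	1	0	212	8.85	22.1573	FKQVVQILTG
ZmVQ43	GRMZM2G036980	chr8	120149428	120150492	1	0	156	5.42	15.6671	FRALVQELTG
ZmVQ44	GRMZM2G180668	chr8	123810520	123811466	1	0	220	10.06	23.1894	FKQVVQRLTG
ZmVQ45	AC203294.3_FG012	chr8	171193955	171194488	1	0	178	5.65	18.8565	FRALVQELTG
ZmVQ46	GRMZM5G800535	chr9	18534327	18534790	1	0	142	6.57	14.4858	FKDVVQWLTG
ZmVQ47	GRMZM2G374336	chr9	44338927	44339600	1	0	176	11.24	18.1407	FRAMVQRVTG
ZmVQ48	GRMZM5G849527	chr9	44340019	44340462	3	0	123	10.03	12.7896	FRAMVQRVTG
ZmVQ49	GRMZM5G864059	chr9	44341110	44341553	3	0	123	10.03	12.7896	FRAMVQRVTG
ZmVQ50	GRMZM2G138370	chr9	64622801	64623710	1	0	139	6.71	14.8997	FKAVVQRLTG
ZmVQ51	GRMZM2G069169	chr9	89016989	89017775	1	1	209	10.43	21.6114	FMPLVQRLTG
ZmVQ52	GRMZM2G122447	chr9	100304257	100305904	1	0	191	5.05	20.6691	FRDLVQRLTG
ZmVQ53	GRMZM2G333049	chr9	110319842	110320893	1	0	233	7.26	24.0476	FRAMVQQFTG
ZmVQ54	GRMZM2G035531	chr9	119969236	119970106	1	0	272	7.17	27.7747	FRAMVQEFTG
ZmVQ55	GRMZM2G014839	chr9	133482875	133483605	1	0	206	7.01	21.0485	FRAMVQRVTG
ZmVQ56	GRMZM2G129815	chr9	134088631	134089643	1	0	181	6.39	19.3031	FRAVVQELTG
ZmVQ57	GRMZM5G864133	chr9	149545721	149547672	1	1	236	11.14	24.4656	FRDVVQKLTG
ZmVQ58	GRMZM2G180262	chr10	2141505	2142516	1	0	219	7.08	22.2236	FRRMVHQVTG
ZmVQ59	GRMZM2G060720	chr10	115122727	115124234	1	0	300	7.21	30.5445	FMALVQHLTG
ZmVQ60	GRMZM2G064903	chr10	145199393	145200369	1	0	211	8.51	22.1278	FRALVQKLTG
ZmVQ61	GRMZM2G475276	chr10	148934513	148935055	1	0	178	9.91	18.9737	FKSVVQRLTG
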