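gene	pos	x_allele	y_allele	in_cds
g001	60	G	C	TRUE
g001	94	C	A	TRUE
g001	97	G	C	TRUE
g001	199	T	C	TRUE
g001	313	G	T	TRUE
g001	363	G	C	TRUE
g001	442	G	A	TRUE
g001	470	G	T	TRUE
g001	479	G	C	TRUE
g001	523	T	A	TRUE
g001	612	T	A	TRUE
g001	657	C	G	TRUE
g001	754	C	A	FALSE
g001	775	A	C	FALSE
g002	57	G	C	TRUE
g002	147	G	T	TRUE
g002	232	A	C	TRUE
g002	280	T	C	TRUE
g002	308	T	A	TRUE
g002	385	T	C	TRUE
g002	442	G	A	TRUE
g002	457	C	G	FALSE
g002	459	A	C	FALSE
g002	551	T	A	FALSE
g002	582	A	G	FALSE
g002	647	T	A	FALSE
g002	689	C	G	FALSE
g002	697	C	T	FALSE
g002	725	T	C	FALSE
g002	969	C	T	FALSE
g002	972	C	G	FALSE
g002	1053	A	T	FALSE
g002	1067	T	A	FALSE
g002	1083	C	A	FALSE
g003	141	A	G	TRUE
g003	151	T	A	TRUE
g003	163	C	T	TRUE
g003	258	A	C	TRUE
g003	342	C	G	TRUE
g003	375	A	G	TRUE
g003	429	T	C	TRUE
g003	457	G	A	FALSE
g004	40	T	A	TRUE
g004	102	T	A	TRUE
g004	132	C	T	TRUE
g004	415	C	G	TRUE
g004	422	A	T	TRUE
g004	542	G	A	TRUE
g004	605	G	C	TRUE
g004	779	T	C	FALSE
g004	883	C	T	FALSE
g004	905	C	G	FALSE
g004	1184	A	C	FALSE
g004	1197	C	T	FALSE
g004	1216	T	C	FALSE
g005	17	A	C	TRUE
g005	71	T	C	TRUE
g005	100	A	G	TRUE
g005	197	T	C	TRUE
g005	201	A	T	TRUE
g005	356	G	C	TRUE
g005	366	T	C	TRUE
g005	436	G	A	TRUE
g005	439	G	C	TRUE
g005	475	A	G	TRUE
g005	505	G	T	TRUE
g005	614	A	C	TRUE
g005	632	A	T	TRUE
g005	713	C	T	TRUE
g005	729	C	T	TRUE
g005	863	A	C	TRUE
g005	948	G	C	FALSE
g005	980	A	G	FALSE
g005	989	A	T	FALSE
g005	1063	G	C	FALSE
g005	1297	A	G	FALSE
g005	1354	G	T	FALSE
g005	1355	A	C	FALSE
g005	1376	C	T	FALSE
g006	51	A	C	TRUE
g006	146	G	T	TRUE
g006	151	T	G	TRUE
g006	166	C	T	TRUE
g006	229	G	C	TRUE
g006	256	C	G	TRUE
g006	262	C	A	TRUE
g006	270	T	C	TRUE
g006	286	C	A	TRUE
g006	533	G	A	FALSE
g006	618	G	C	FALSE
g006	689	G	C	FALSE
g007	58	G	T	TRUE
g007	61	T	C	TRUE
g007	99	T	A	TRUE
g007	124	C	G	TRUE
g007	147	G	C	TRUE
g007	201	T	C	TRUE
g007	257	C	A	TRUE
g007	271	G	C	TRUE
g007	330	G	T	TRUE
g007	346	T	G	TRUE
g007	371	C	G	TRUE
g007	382	C	A	TRUE
g007	389	C	A	TRUE
g007	423	G	T	TRUE
g007	424	C	A	TRUE
g007	499	T	C	FALSE
g007	539	T	C	FALSE
g007	624	A	C	FALSE
g007	695	C	G	FALSE
g007	765	A	T	FALSE
g007	853	C	T	FALSE
g008	85	T	C	TRUE
g008	95	G	C	TRUE
g008	127	A	C	TRUE
g008	152	A	G	TRUE
g008	203	A	C	TRUE
g008	289	A	G	TRUE
g008	314	C	T	TRUE
g008	373	C	A	TRUE
g008	431	T	A	TRUE
g008	466	C	A	FALSE
g008	484	T	G	FALSE
g008	501	A	G	FALSE
g008	587	T	C	FALSE
g008	606	C	G	FALSE
g008	629	G	A	FALSE
g008	636	G	T	FALSE
g008	695	G	T	FALSE
g008	756	T	A	FALSE
g008	766	T	A	FALSE
g008	840	C	A	FALSE
g008	879	T	A	FALSE
g009	92	C	A	TRUE
g009	122	T	A	TRUE
g009	180	C	A	TRUE
g009	184	A	G	TRUE
g009	237	A	G	TRUE
g009	392	C	G	TRUE
g009	485	A	T	FALSE
g009	495	A	T	FALSE
g009	539	A	T	FALSE
g009	618	A	C	FALSE
g009	621	A	T	FALSE
g010	132	A	C	TRUE
g010	208	G	C	TRUE
g010	263	A	C	TRUE
g010	319	G	A	TRUE
g010	338	G	C	TRUE
g010	351	T	G	TRUE
g010	423	C	A	TRUE
g010	600	A	T	TRUE
g010	683	C	G	TRUE
g010	709	C	T	TRUE
g010	778	G	T	TRUE
g010	867	T	C	FALSE
g010	900	G	A	FALSE
g010	960	T	G	FALSE
g010	967	A	C	FALSE
g010	972	C	G	FALSE
g010	1027	T	C	FALSE
g010	1093	C	A	FALSE
g010	1251	T	C	FALSE
g010	1257	G	T	FALSE
g010	1288	G	T	FALSE
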