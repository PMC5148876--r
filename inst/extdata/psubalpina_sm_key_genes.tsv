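# Curated secondary-metabolite key genes of the Phialocephala subalpina
# genome with published class labels. `architecture` is the ordered domain
# string of PKS/NRPS-type enzymes; genes identified only by InterPro
# accessions (type III PKS, DMATS, terpene synthases) carry an `ipr_class`
# pass-through label instead.
gene	class	length_aa	architecture	ipr_class
PAC_02750	NRPS-like	1167	A-T-R	
PAC_02944	NRPS-like	1049	A-T-R	
PAC_01324	NRPS-like	1047	A-T-R	
PAC_02391	NRPS-like	1023	A-T-R	
PAC_03877	NRPS-like	1117	A-T-R	
PAC_04959	NRPS-like	1038	A-T-R	
PAC_05733	NRPS-like	1008	A-T-R	
PAC_07003	NRPS-like	1054	A-T-R	
PAC_12811	NRPS-like	1054	A-T-R	
PAC_17490	NRPS-like	1065	A-T-R	
PAC_19780	NRPS-like	1050	A-T-R	
PAC_02202	NRPS-like	1227	A-T-R-Kinase	
PAC_08842	NRPS-like	1345	A-T-R-KR	
PAC_08910	NRPS-like	1013	A-T-TE	
PAC_14584	NRPS-like	979	A-T-TE	
PAC_19640	NRPS-like	1394	A-T-DUF	
PAC_12359	NRPS-like	1655	A-T-DUF	
PAC_05248	NRPS	4676	A-T-C-A-T-C-A-T-C-T-C-T-C	
PAC_13158	NRPS	4838	A-T-C-A-T-C-T-C-A-T-C-T-C-T-C	
PAC_15746	NRPS	1639	A-T-C-T-C	
PAC_20134	NRPS	4692	C-A-T-C-A-T-C-A-T-C-A-T-C-T	
PAC_16560	NRPS	565	A-T-C	
PAC_16746	NRPS	1207	A-T-C	
PAC_19282	NRPS	1220	A-T-C	
PAC_02326	PKS-NRPS hybrid	3974	KS-AT-DH-MT-KR-T-C-A-T-R	
PAC_08246	PKS-NRPS hybrid	3965	KS-AT-DH-MT-KR-T-C-A-T-R	
PAC_01338	nonreducing type I PKS	2542	SAT-KS-AT-PT-T-MT-TE	
PAC_02435	nonreducing type I PKS	2498	SAT-KS-AT-PT-T-MT-TE	
PAC_03302	nonreducing type I PKS	2223	KS-AT-DH-T-TE	
PAC_03589	nonreducing type I PKS	1670	KS-AT-PT-T-TE	
PAC_07895	nonreducing type I PKS	2171	SAT-KS-AT-PT-T-T-TE	
PAC_08751	nonreducing type I PKS	2099	SAT-KS-AT-PT-T-T-TE	
PAC_10081	nonreducing type I PKS	2125	SAT-KS-AT-PT-T-T-TE	
PAC_11435	nonreducing type I PKS	2169	SAT-KS-AT-PT-T-T-TE	
PAC_00199	reducing type I PKS	2694	KS-AT-DH-MT-ER-KR-T	
PAC_00310	reducing type I PKS	2283	KS-AT-DH-ER-KR-T	
PAC_01646	reducing type I PKS	1687	AT-DH-MT-ER-KR-T	
PAC_04883	reducing type I PKS	2239	KS-AT-DH-ER-KR-T	
PAC_06141	reducing type I PKS	2258	KS-AT-DH-ER-KR-T	
PAC_10762	reducing type I PKS	3173	KS-AT-DH-MT-ER-KR-T-Acyltransferase	
PAC_11350	reducing type I PKS	3203	KS-AT-DH-MT-ER-KR-T-Acyltransferase	
PAC_14253	reducing type I PKS	2590	KS-AT-DH-MT-ER-KR-T	
PAC_14645	reducing type I PKS	2274	KS-AT-DH-ER-KR-T	
PAC_16276	reducing type I PKS	3140	KS-AT-DH-MT-ER-KR-T-Acyltransferase	
PAC_17799	reducing type I PKS	2411	KS-AT-DH-ER-KR-T	
PAC_19082	reducing type I PKS	2581	KS-AT-DH-MT-ER-KR-T	
PAC_19990	reducing type I PKS	2970	KS-AT-DH-MT-KR-T-C	
PAC_10712	reducing type I PKS	1430	KS-AT-TH-KR-T	
PAC_02116	type III PKS	479		type III PKS
PAC_15749	DMATS	538		DMATS
PAC_05884	terpene	483		terpene
PAC_13844	terpene	593		terpene
PAC_15298	terpene	557		terpene
PAC_01018	terpene	338		terpene
PAC_04028	terpene	331		terpene
PAC_11164	terpene	466		terpene
PAC_12198	terpene	392		terpene
PAC_16221	terpene	336		terpene
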