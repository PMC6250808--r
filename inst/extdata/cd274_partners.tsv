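group	gene	pearson_r	p_value	fdr	style
control	IL2RA	0.9732955	9.98E-06	0.0001717	Positive
control	PRKCQ	0.9687537	1.72E-05	0.0002295	Positive
control	CD28	0.9636073	2.92E-05	0.0003181	Positive
control	RRM2	0.9579704	4.81E-05	0.0004146	Positive
control	CCR5	0.9491639	9.28E-05	0.0006202	Positive
control	SH2D1A	0.9451843	0.0001203	0.0007168	Positive
control	SOD2	0.9420219	0.000146	0.000804	Positive
control	CDK1	0.9395096	0.0001689	0.0008682	Positive
control	EIF2AK2	0.9374203	0.0001898	0.0009311	Positive
control	STAT1	0.935628	0.0002092	0.0009775	Positive
control	IL7R	0.9274773	0.0003149	0.0012596	Positive
control	PTPRC	0.9266246	0.0003278	0.0012927	Positive
control	CCNB2	0.9249148	0.0003547	0.0013297	Positive
control	TLR4	0.9172249	0.0004951	0.0016521	Positive
control	CD86	0.9127902	0.0005917	0.0018396	Positive
control	SELE	0.90586	0.0007679	0.0021744	Positive
control	CCR1	0.9043284	0.0008113	0.0022361	Positive
control	ACSL4	0.8998301	0.0009485	0.0024332	Positive
control	CHEK1	0.897294	0.0010326	0.0025454	Positive
control	IFIH1	0.8901775	0.0012961	0.0029215	Positive
control	IL6ST	0.8842571	0.0015483	0.0032586	Positive
control	CASP8	0.8832669	0.0015936	0.003319	Positive
control	TLR3	0.8818203	0.0016613	0.0033809	Positive
control	IL19	0.8780748	0.001846	0.0036114	Positive
control	FCGR1C	0.8780748	0.001846	0.0036114	Positive
control	ATR	0.8765252	0.0019264	0.0036989	Positive
control	JAK2	0.8721792	0.0021647	0.0039831	Positive
control	FAR1	0.8709298	0.0022368	0.0040843	Positive
control	CCNB1	0.8690707	0.0023472	0.0042117	Positive
control	AOX1	0.8679496	0.0024155	0.0042772	Positive
control	CTLA4	0.8556067	0.003261	0.0051653	Positive
control	TLR6	0.854854	0.0033184	0.0052137	Positive
control	IL12RB1	0.8535532	0.0034191	0.0052649	Positive
control	PDCD1LG2	0.8534694	0.0034256	0.0052681	Positive
control	ATM	0.8529131	0.0034694	0.0052953	Positive
control	CD3G	0.8522091	0.0035253	0.0053394	Positive
control	STAT4	0.8517455	0.0035625	0.0053668	Positive
control	TNFSF14	0.8484067	0.0038381	0.0056231	Positive
control	TLR1	0.8479869	0.0038737	0.0056293	Positive
control	UBE2T	0.8459649	0.0040487	0.0058049	Positive
control	POLK	0.8386417	0.0047275	0.0063276	Positive
control	BRIP1	0.8381076	0.0047799	0.0063603	Positive
control	IL26	0.8170625	0.0071733	0.0081403	Positive
control	IL17A	0.8052876	0.0088147	0.0092264	Positive
control	CD80	0.8052343	0.0088226	0.0092292	Positive
control	TNFSF8	0.8038217	0.0090353	0.0093678	Positive
control	CCL4	0.7989072	0.0098021	0.0098881	Positive
control	CD209	0.9464572	0.000111	0.0006948	Positive
control	CD226	0.8807744	0.0017115	0.0034349	Positive
control	CXCL1	0.8978401	0.0010141	0.0025218	Positive
control	CYP7B1	0.9328796	0.0002415	0.0010628	Positive
control	FANCI	0.9250662	0.0003522	0.0013281	Positive
control	ICOS	0.9539927	6.57E-05	0.0004822	Positive
control	IFN-γ	0.8780748	0.001846	0.0036114	Positive
control	PIK3CG	0.956161	5.56E-05	0.0004454	Positive
control	REV3L	0.9490468	9.35E-05	0.0006202	Positive
case	EEF1G	-0.675341	0.002101	0.0037489	Negative
case	IL12B	0.901116	3.36E-07	9.64E-06	Positive
case	CCL20	0.8556256	5.97E-06	7.67E-05	Positive
case	CCL7	0.7927733	8.72E-05	0.0004859	Positive
case	DDX58	0.7621884	0.0002362	0.0009399	Positive
case	FOS	0.7618061	0.0002389	0.0009452	Positive
case	IL19	0.664267	0.0026406	0.0043512	Positive
case	IL1RAP	0.6642463	0.0026417	0.0043512	Positive
case	IFIH1	0.6626158	0.00273	0.0044301	Positive
case	STAT1	0.6597544	0.0028909	0.0045988	Positive
case	CXCL10	0.6595464	0.0029029	0.0046016	Positive
case	CXCL11	0.6376404	0.004416	0.0060023	Positive
case	NOS2	0.628715	0.0051931	0.0066592	Positive
case	CXCL1	0.6198472	0.006072	0.0072939	Positive
case	CXCL2	0.6630916	0.002704	0.0044047	Positive
case	LOC100288533	0.6543663	0.003215	0.0048891	Positive
case	LOC642934	0.6395765	0.0042606	0.0058708	Positive
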