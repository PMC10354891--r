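exposure	outcome	nSNPs	method	beta	ci_low	ci_high	se	pval
COVID-19 vs. general population	Thickness of caudal middle frontal gyrus	28	IVW	-0.0044	-0.0087	-0.0002	0.0022	0.0412
Hospitalized COVID-19 vs. general population	Thickness of lateral orbitofrontal gyrus	26	IVW	-0.0049	-0.0093	-0.0004	0.0023	0.0328
Hospitalized COVID-19 vs. general population	Surface area of middle temporal gyrus	26	IVW	-10.8855	-20.5067	-1.2642	4.9088	0.0266
Hospitalized COVID-19 vs. non-hospitalized COVID-19	Thickness of rostral middle frontal gyrus	20	IVW	-0.0022	-0.0037	-0.0008	0.0008	0.0032
Severe COVID-19 vs. general population	Thickness of cuneus	39	IVW	-0.0024	-0.0043	-0.0004	0.0010	0.0168
Severe COVID-19 vs. general population	Volume of hippocampus	36	IVW	-15.9127	-26.2067	-5.6188	5.2520	0.0024
Severe COVID-19 with respiratory failure vs. general population	Thickness of rostral middle frontal gyrus	14	IVW	-0.0014	-0.0025	-0.0002	0.0006	0.0190
Severe COVID-19 with respiratory failure vs. general population	Thickness of caudal middle frontal gyrus	14	IVW	-0.0017	-0.0032	-0.0002	0.0008	0.0244
Severe COVID-19 with respiratory failure vs. general population	Surface area of pericalcarine	14	IVW	-2.6628	-5.3167	-0.0089	1.3540	0.0492
Severe COVID-19 with respiratory failure vs. general population	Surface area of superior parietal gyrus	14	IVW	-5.6310	-11.0270	-0.2348	2.7532	0.0408
Critical COVID-19 vs. general population	Thickness of middle temporal gyrus	92	IVW	-0.0002	-0.0003	0	0.0001	0.0462
Critical COVID-19 vs. general population	Surface area of middle temporal gyrus	92	IVW	-0.5261	-0.9793	-0.0729	0.2312	0.0229
Critical COVID-19 vs. general population	Surface area of parahippocampal gyrus	92	IVW	-0.1473	-0.2802	-0.0145	0.0678	0.0297
Critical COVID-19 vs. general population	Surface area of insula	92	IVW	0.3832	0.1192	0.6472	0.1347	0.0044
Severe COVID-19 vs. general population	Volume of hippocampus	36	Weighted median	-15.8282	NA	NA	7.8174	0.0429
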