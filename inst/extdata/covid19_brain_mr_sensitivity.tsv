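exposure	outcome	nSNPs	q_stat	q_pval	egger_intercept	egger_intercept_pval	presso_pval
COVID-19 vs. general population	Thickness of caudal middle frontal gyrus	28	36.5379	0.1040	-0.0003	0.5605	0.0470
Hospitalized COVID-19 vs. general population	Thickness of lateral orbitofrontal gyrus	26	22.6627	0.5973	-0.0002	0.7648	0.5780
Hospitalized COVID-19 vs. general population	Surface area of middle temporal gyrus	26	25.8789	0.4141	-0.8634	0.5589	0.4400
Hospitalized COVID-19 vs. non-hospitalized COVID-19	Thickness of rostral middle frontal gyrus	20	15.6886	0.6779	-0.0002	0.7609	0.6830
Severe COVID-19 vs. general population	Thickness of cuneus	39	43.8548	0.2371	0.0006	0.2634	0.2640
Severe COVID-19 vs. general population	Volume of hippocampus	36	34.0941	0.5117	-3.1943	0.2435	0.5160
Severe COVID-19 with respiratory failure vs. general population	Thickness of rostral middle frontal gyrus	14	6.7957	0.9124	0	0.9628	0.8080
Severe COVID-19 with respiratory failure vs. general population	Thickness of caudal middle frontal gyrus	14	16.9137	0.2033	-0.0005	0.5768	0.2750
Severe COVID-19 with respiratory failure vs. general population	Surface area of pericalcarine	14	7.5854	0.8695	1.6803	0.2526	0.9240
Severe COVID-19 with respiratory failure vs. general population	Surface area of superior parietal gyrus	14	10.6660	0.6393	1.6369	0.5755	0.7390
Critical COVID-19 vs. general population	Thickness of middle temporal gyrus	92	76.1485	0.8680	0.0001	0.6839	0.8910
Critical COVID-19 vs. general population	Surface area of middle temporal gyrus	92	138.3960	0.0010	1.1069	0.2578	0.0010
Critical COVID-19 vs. general population	Surface area of parahippocampal gyrus	92	120.8511	0.0199	0.2390	0.4051	0.0130
Critical COVID-19 vs. general population	Surface area of insula	92	96.8868	0.3169	0.0544	0.9242	0.3400
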