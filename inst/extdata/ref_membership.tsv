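name	u_PC1	u_PC2	u_PC3	D	rank
Huangluo	1.000	0.589	0.381	0.827	1
Bertone	0.922	0.877	0.272	0.824	2
Agostono	0.981	0.687	0.290	0.823	3
Cigalon	0.921	0.432	0.715	0.787	4
Banat 2951	0.798	0.395	0.782	0.709	5
Yangbiguangkeludao	0.684	0.386	0.386	0.579	6
Xiannan 22	0.088	1.000	1.000	0.409	7
Koshihikari	0.239	0.495	0.676	0.354	8
Nipponbare	0.278	0.099	0.501	0.270	9
Banat 725	0.281	0.000	0.600	0.263	10
Jianan 8	0.092	0.272	0.375	0.169	11
Shanfuliya	0.000	0.696	0.000	0.150	12
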