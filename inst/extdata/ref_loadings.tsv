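index	PC1	PC2	PC3
STS	0.972	0.053	-0.075
RSPAD	0.922	-0.260	0.050
Fm	0.943	0.176	0.129
Fv/Fm	0.789	0.450	-0.018
Y	0.873	0.314	-0.206
NPQ	0.940	0.288	-0.092
ETR	0.895	0.270	-0.086
SNa+	-0.663	-0.457	-0.360
RNa+	-0.454	0.225	0.800
SK+	0.496	-0.710	0.395
RK+	0.456	-0.796	0.121
SNa+/K+	-0.684	0.374	-0.555
RNa+/K+	-0.528	0.663	0.515
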