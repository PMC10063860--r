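component	eigenvalue	proportion	cumulative
PC1	7.601	58.471	58.471
PC2	2.536	19.509	77.980
PC3	1.596	12.273	90.254
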