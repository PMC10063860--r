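no	name	origin	tolerance	d_st	sts
1	Bertone	Portugal	salt-tolerant	0.810	7.5
2	Agostono	Italy	salt-tolerant	0.716	7.2
3	Huangluo	Russia	salt-tolerant	0.681	6.6
4	Yangbiguangkeludao	Yunnan, China	salt-tolerant	0.627	6.3
5	Cigalon	France	salt-tolerant	0.621	6.5
6	Banat 2951	Australia	salt-tolerant	0.612	6.5
7	Shanfuliya	Guinea	salt-sensitive	0.545	1.4
8	Nipponbare	Japan	salt-sensitive	0.521	2.9
9	Xiannan 22	Korea	salt-sensitive	0.497	1.7
10	Koshihikari	Japan	salt-sensitive	0.312	1.8
11	Jianan 8	Taiwan, China	salt-sensitive	0.261	2.2
12	Banat 725	Australia	salt-sensitive	0.252	2.6
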