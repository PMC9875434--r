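letter	kd	flex	hphob	hphil	side_mass	mw_free	grantham_c	grantham_p	grantham_v
A	1.8	0.984	0.62	-0.5	15	89.0932	0	8.1	31
C	2.5	0.906	0.29	-1.0	47	121.1582	2.75	5.5	55
D	-3.5	1.068	-0.90	3.0	59	133.1027	1.38	13.0	54
E	-3.5	1.094	-0.74	3.0	73	147.1293	0.92	12.3	83
F	2.8	0.915	1.19	-2.5	91	165.1891	0	5.2	132
G	-0.4	1.031	0.48	0.0	1	75.0666	0.74	9.0	3
H	-3.2	0.950	-0.40	-0.5	82	155.1546	0.58	10.4	96
I	4.5	0.927	1.38	-1.8	57	131.1729	0	5.2	111
K	-3.9	1.102	-1.50	3.0	73	146.1876	0.33	11.3	119
L	3.8	0.935	1.06	-1.8	57	131.1729	0	4.9	111
M	1.9	0.952	0.64	-1.3	75	149.2113	0	5.7	105
N	-3.5	1.048	-0.78	0.2	58	132.1179	1.33	11.6	56
P	-1.6	1.049	0.12	0.0	42	115.1305	0.39	8.0	32.5
Q	-3.5	1.037	-0.85	0.2	72	146.1445	0.89	10.5	85
R	-4.5	1.008	-2.53	3.0	101	174.2010	0.65	10.5	124
S	-0.8	1.046	-0.18	0.3	31	105.0926	1.42	9.2	32
T	-0.7	0.997	-0.05	-0.4	45	119.1192	0.71	8.6	61
V	4.2	0.931	1.08	-1.5	43	117.1463	0	5.9	84
W	-0.9	0.904	0.81	-3.4	130	204.2252	0.13	5.4	170
Y	-1.3	0.929	0.26	-2.3	107	181.1885	0.20	6.2	136
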