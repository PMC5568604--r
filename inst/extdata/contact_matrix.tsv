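	A	R	N	D	C	Q	E	G	H	I	L	K	M	F	P	S	T	W	Y	V
A	-0.486	1.215	0.945	0.945	-0.675	0.945	0.945	0.108	0.864	-1.215	-1.026	1.053	-0.513	-0.756	0.432	0.216	0.189	0.243	0.351	-1.134
R	1.215	-3.0375	-2.3625	-2.3625	1.6875	-2.3625	-2.3625	-0.27	-2.16	3.0375	2.565	-2.6325	1.2825	1.89	-1.08	-0.54	-0.4725	-0.6075	-0.8775	2.835
N	0.945	-2.3625	-1.8375	-1.8375	1.3125	-1.8375	-1.8375	-0.21	-1.68	2.3625	1.995	-2.0475	0.9975	1.47	-0.84	-0.42	-0.3675	-0.4725	-0.6825	2.205
D	0.945	-2.3625	-1.8375	-1.8375	1.3125	-1.8375	-1.8375	-0.21	-1.68	2.3625	1.995	-2.0475	0.9975	1.47	-0.84	-0.42	-0.3675	-0.4725	-0.6825	2.205
C	-0.675	1.6875	1.3125	1.3125	-0.9375	1.3125	1.3125	0.15	1.2	-1.6875	-1.425	1.4625	-0.7125	-1.05	0.6	0.3	0.2625	0.3375	0.4875	-1.575
Q	0.945	-2.3625	-1.8375	-1.8375	1.3125	-1.8375	-1.8375	-0.21	-1.68	2.3625	1.995	-2.0475	0.9975	1.47	-0.84	-0.42	-0.3675	-0.4725	-0.6825	2.205
E	0.945	-2.3625	-1.8375	-1.8375	1.3125	-1.8375	-1.8375	-0.21	-1.68	2.3625	1.995	-2.0475	0.9975	1.47	-0.84	-0.42	-0.3675	-0.4725	-0.6825	2.205
G	0.108	-0.27	-0.21	-0.21	0.15	-0.21	-0.21	-0.024	-0.192	0.27	0.228	-0.234	0.114	0.168	-0.096	-0.048	-0.042	-0.054	-0.078	0.252
H	0.864	-2.16	-1.68	-1.68	1.2	-1.68	-1.68	-0.192	-1.536	2.16	1.824	-1.872	0.912	1.344	-0.768	-0.384	-0.336	-0.432	-0.624	2.016
I	-1.215	3.0375	2.3625	2.3625	-1.6875	2.3625	2.3625	0.27	2.16	-3.0375	-2.565	2.6325	-1.2825	-1.89	1.08	0.54	0.4725	0.6075	0.8775	-2.835
L	-1.026	2.565	1.995	1.995	-1.425	1.995	1.995	0.228	1.824	-2.565	-2.166	2.223	-1.083	-1.596	0.912	0.456	0.399	0.513	0.741	-2.394
K	1.053	-2.6325	-2.0475	-2.0475	1.4625	-2.0475	-2.0475	-0.234	-1.872	2.6325	2.223	-2.2815	1.1115	1.638	-0.936	-0.468	-0.4095	-0.5265	-0.7605	2.457
M	-0.513	1.2825	0.9975	0.9975	-0.7125	0.9975	0.9975	0.114	0.912	-1.2825	-1.083	1.1115	-0.5415	-0.798	0.456	0.228	0.1995	0.2565	0.3705	-1.197
F	-0.756	1.89	1.47	1.47	-1.05	1.47	1.47	0.168	1.344	-1.89	-1.596	1.638	-0.798	-1.176	0.672	0.336	0.294	0.378	0.546	-1.764
P	0.432	-1.08	-0.84	-0.84	0.6	-0.84	-0.84	-0.096	-0.768	1.08	0.912	-0.936	0.456	0.672	-0.384	-0.192	-0.168	-0.216	-0.312	1.008
S	0.216	-0.54	-0.42	-0.42	0.3	-0.42	-0.42	-0.048	-0.384	0.54	0.456	-0.468	0.228	0.336	-0.192	-0.096	-0.084	-0.108	-0.156	0.504
T	0.189	-0.4725	-0.3675	-0.3675	0.2625	-0.3675	-0.3675	-0.042	-0.336	0.4725	0.399	-0.4095	0.1995	0.294	-0.168	-0.084	-0.0735	-0.0945	-0.1365	0.441
W	0.243	-0.6075	-0.4725	-0.4725	0.3375	-0.4725	-0.4725	-0.054	-0.432	0.6075	0.513	-0.5265	0.2565	0.378	-0.216	-0.108	-0.0945	-0.1215	-0.1755	0.567
Y	0.351	-0.8775	-0.6825	-0.6825	0.4875	-0.6825	-0.6825	-0.078	-0.624	0.8775	0.741	-0.7605	0.3705	0.546	-0.312	-0.156	-0.1365	-0.1755	-0.2535	0.819
V	-1.134	2.835	2.205	2.205	-1.575	2.205	2.205	0.252	2.016	-2.835	-2.394	2.457	-1.197	-1.764	1.008	0.504	0.441	0.567	0.819	-2.646
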