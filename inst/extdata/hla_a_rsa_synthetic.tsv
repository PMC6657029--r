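structure_id	protein	position	rsa
synt1	HLA-A	205	16.72
synt1	HLA-A	206	17.06
synt1	HLA-A	207	7.29
synt1	HLA-A	208	15.46
synt1	HLA-A	209	12.63
synt1	HLA-A	210	10.79
synt1	HLA-A	211	14.05
synt1	HLA-A	212	5.02
synt1	HLA-A	229	30.4
synt1	HLA-A	230	31.74
synt1	HLA-A	231	24.82
synt1	HLA-A	232	32.14
synt2	HLA-A	205	17.02
synt2	HLA-A	206	6.83
synt2	HLA-A	207	9.93
synt2	HLA-A	208	17.1
synt2	HLA-A	209	17.67
synt2	HLA-A	210	4.76
synt2	HLA-A	211	10.12
synt2	HLA-A	212	11.4
synt2	HLA-A	229	37.31
synt2	HLA-A	230	15.88
synt2	HLA-A	231	39.69
synt2	HLA-A	232	38.51
synt3	HLA-A	205	4.24
synt3	HLA-A	206	10.71
synt3	HLA-A	207	8.85
synt3	HLA-A	208	16.59
synt3	HLA-A	209	9.7
synt3	HLA-A	210	15.54
synt3	HLA-A	211	14.06
synt3	HLA-A	212	15.17
synt3	HLA-A	229	22.87
synt3	HLA-A	230	31.18
synt3	HLA-A	231	12.11
synt3	HLA-A	232	35.32
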