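Gene	Chr	Length	Count	Frequency
OR51F23	2	930	3	3.23e-03
L1TD1	5	5205	2	3.84e-04
MRPL21	1	13363	4	2.99e-04
CASP6	3	13647	4	2.93e-04
ZNF777	1	22897	6	2.62e-04
WDCP	1	19464	5	2.57e-04
DLA-79	1	27794	6	2.16e-04
GALC	8	57150	9	1.57e-04
MKI67	2	26464	4	1.51e-04
NIPSNAP2	6	33134	5	1.51e-04
ACTR10	8	31824	4	1.26e-04
CISD2	3	16071	2	1.24e-04
GCM1	1	16477	2	1.21e-04
CKLF	5	16928	2	1.18e-04
FAM98B	3	34924	4	1.15e-04
PRDM4	1	26340	3	1.14e-04
OR6C53	3	17700	2	1.13e-04
TRPV1	9	26955	3	1.11e-04
NUDT6	1	31071	3	9.66e-05
LAPTM4B	1	86062	8	9.30e-05
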