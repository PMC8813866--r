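rna_name	length	algorithm	x	y	mcc
d.5.e.C.carpio	120	partition	0.66	0.68	0.67
d.5.e.C.carpio	120	nussinov	0.64	0.59	0.61
d.5.e.C.carpio	120	assembly	0.61	0.63	0.62
a.I1.e.L.dispersa	218	partition	0.49	0.44	0.46
a.I1.e.L.dispersa	218	nussinov	0.46	0.43	0.44
a.I1.e.L.dispersa	218	assembly	0.62	0.63	0.62
a.I1.e.P.inouyei	380	partition	0.53	0.59	0.56
a.I1.e.P.inouyei	380	nussinov	0.36	0.29	0.32
a.I1.e.P.inouyei	380	assembly	0.68	0.65	0.66
a.I1.e.Staurastrum.sp	423	partition	0.45	0.49	0.47
a.I1.e.Staurastrum.sp	423	nussinov	0.30	0.29	0.30
a.I1.e.Staurastrum.sp	423	assembly	0.53	0.51	0.52
b.I1.e.H.rubra	543	partition	0.42	0.29	0.35
b.I1.e.H.rubra	543	nussinov	0.19	0.17	0.17
b.I1.e.H.rubra	543	assembly	0.51	0.46	0.48
a.16.m.L.tarentolae	670	partition	0.16	0.21	0.18
a.16.m.L.tarentolae	670	nussinov	0.15	0.18	0.16
a.16.m.L.tarentolae	670	assembly	0.23	0.24	0.23
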