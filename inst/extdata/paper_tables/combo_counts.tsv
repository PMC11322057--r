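maternal_rsid	maternal_class	fetal_rsid	fetal_class	case	control
rs649216	CC	rs9380142	AA/GA	43	27
rs649216	CC	rs9380142	GG	10	26
rs649216	CT/TT	rs9380142	AA/GA	15	19
rs649216	CT/TT	rs9380142	GG	6	8
rs1051456	CC	rs9380142	AA/GA	9	15
rs1051456	CC	rs9380142	GG	4	8
rs1051456	GC/GG	rs9380142	AA/GA	49	31
rs1051456	GC/GG	rs9380142	GG	12	26
rs34785252	CC	rs9380142	AA/GA	9	16
rs34785252	CC	rs9380142	GG	4	8
rs34785252	CA/AA	rs9380142	AA/GA	49	30
rs34785252	CA/AA	rs9380142	GG	12	26
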