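role	rsid	gene	major	minor	case_minor	case_total	control_minor	control_total
mother	rs649216	KIR2DL4	C	T	23	148	31	160
mother	rs1051456	KIR2DL4	C	G	90	148	80	160
mother	rs34785252	KIR2DL4	C	A	62	148	75	160
mother	rs9380142	HLA-G	G	A	61	148	80	160
mother	rs1063320	HLA-G	C	G	53	148	60	160
mother	rs1630185	HLA-G	A	G	72	148	66	160
mother	rs1130363	HLA-G	G	A	73	148	66	160
father	rs9380142	HLA-G	G	A	45	112	52	156
father	rs1063320	HLA-G	C	G	48	112	72	156
father	rs1630185	HLA-G	A	G	56	112	97	156
father	rs1130363	HLA-G	G	A	56	112	97	156
offspring	rs9380142	HLA-G	G	A	85	148	62	160
offspring	rs1063320	HLA-G	C	G	74	148	57	160
offspring	rs1630185	HLA-G	A	G	61	148	75	160
offspring	rs1130363	HLA-G	G	A	62	148	68	160
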