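role	rsid	case_AA	case_AB	case_BB	control_AA	control_AB	control_BB
mother	rs649216	53	19	2	53	23	4
mother	rs1051456	13	32	29	23	34	23
mother	rs34785252	25	36	13	26	33	21
mother	rs9380142	31	25	18	24	32	24
mother	rs1063320	37	21	16	34	32	14
mother	rs1630185	18	40	16	27	40	13
mother	rs1130363	18	39	17	27	40	13
father	rs9380142	25	17	14	37	30	11
father	rs1063320	26	12	18	27	30	21
father	rs1630185	18	20	18	28	41	9
father	rs1130363	18	20	18	28	41	9
offspring	rs9380142	16	31	27	34	30	16
offspring	rs1063320	19	36	19	37	29	14
offspring	rs1630185	24	39	11	20	45	15
offspring	rs1130363	22	42	10	27	38	15
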