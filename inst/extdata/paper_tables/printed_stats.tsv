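table	row_id	statistic	printed
allele	mother rs649216	or	0.765
allele	mother rs649216	chi2	0.781
allele	mother rs1051456	or	1.551
allele	mother rs1051456	chi2	2.854
allele	mother rs34785252	or	0.817
allele	mother rs34785252	chi2	0.773
allele	mother rs9380142	or	1.426
allele	mother rs9380142	chi2	2.389
allele	mother rs1063320	or	0.929
allele	mother rs1063320	chi2	0.094
allele	mother rs1630185	or	1.349
allele	mother rs1630185	chi2	1.701
allele	mother rs1130363	or	1.386
allele	mother rs1130363	chi2	2.024
allele	father rs9380142	or	1.389
allele	father rs9380142	chi2	1.322
allele	father rs1063320	or	0.875
allele	father rs1063320	chi2	0.286
allele	father rs1630185	or	1.644
allele	father rs1630185	chi2	3.947
allele	father rs1130363	or	1.644
allele	father rs1130363	chi2	3.947
allele	offspring rs9380142	or	2.802
allele	offspring rs9380142	chi2	19.352
allele	offspring rs1063320	or	1.807
allele	offspring rs1063320	chi2	6.499
allele	offspring rs1630185	or	0.794
allele	offspring rs1630185	chi2	0.998
allele	offspring rs1130363	or	0.975
allele	offspring rs1130363	chi2	0.011
genotype	mother rs649216	p_global	0.725
genotype	mother rs649216	or_dom	0.778
genotype	mother rs649216	or_rec	0.528
genotype	mother rs1051456	p_global	0.196
genotype	mother rs1051456	or_dom	0.626
genotype	mother rs1051456	or_rec	0.528
genotype	mother rs34785252	p_global	0.406
genotype	mother rs34785252	or_dom	0.944
genotype	mother rs34785252	or_rec	0.599
genotype	mother rs9380142	p_global	0.304
genotype	mother rs9380142	or_dom	0.594
genotype	mother rs9380142	or_rec	0.430
genotype	mother rs1063320	p_global	0.314
genotype	mother rs1063320	or_dom	0.739
genotype	mother rs1063320	or_rec	1.300
genotype	mother rs1630185	p_global	0.39
genotype	mother rs1630185	or_dom	1.585
genotype	mother rs1630185	or_rec	1.422
genotype	mother rs1130363	p_global	0.347
genotype	mother rs1130363	or_dom	1.585
genotype	mother rs1130363	or_rec	1.537
genotype	father rs9380142	p_global	0.254
genotype	father rs9380142	or_dom	1.119
genotype	father rs9380142	or_rec	2.030
genotype	father rs1063320	p_global	0.106
genotype	father rs1063320	or_dom	1.182
genotype	father rs1063320	or_rec	1.464
genotype	father rs1630185	p_global	0.010
genotype	father rs1630185	or_dom	1.182
genotype	father rs1630185	or_rec	3.632
genotype	father rs1130363	p_global	0.010
genotype	father rs1130363	or_dom	1.182
genotype	father rs1130363	or_rec	3.632
genotype	offspring rs9380142	p_global	0.010
genotype	offspring rs9380142	or_dom	2.196
genotype	offspring rs9380142	or_rec	1.633
genotype	offspring rs1063320	p_global	0.029
genotype	offspring rs1063320	or_dom	2.491
genotype	offspring rs1063320	or_rec	1.629
genotype	offspring rs1630185	p_global	0.555
genotype	offspring rs1630185	or_dom	0.694
genotype	offspring rs1630185	or_rec	0.757
genotype	offspring rs1130363	p_global	0.477
genotype	offspring rs1130363	or_dom	1.204
genotype	offspring rs1130363	or_rec	0.677
tdt	rs9380142 case all	chi2	2.793
tdt	rs9380142 case mother	chi2	2.882
tdt	rs9380142 case father	chi2	0.5
tdt	rs9380142 control all	chi2	11.111
tdt	rs9380142 control mother	chi2	5.556
tdt	rs9380142 control father	chi2	5.556
tdt	rs1063320 case all	chi2	2.632
tdt	rs1063320 case mother	chi2	2
tdt	rs1063320 case father	chi2	1
tdt	rs1063320 control all	chi2	0.018
tdt	rs1063320 control mother	chi2	0.474
tdt	rs1063320 control father	chi2	0.133
combo	rs649216 x rs9380142	chi2_global	11.308
combo	rs649216 CC:GG	or	0.242
combo	rs649216 CT/TT:AA/GA	or	0.496
combo	rs649216 CT/TT:GG	or	0.471
combo	rs1051456 x rs9380142	chi2_global	11.825
combo	rs1051456 CC:AA/GA	or	0.38
combo	rs1051456 CC:GG	or	0.316
combo	rs1051456 GC/GG:GG	or	0.292
combo	rs34785252 x rs9380142	chi2_global	12.807
combo	rs34785252 CC:AA/GA	or	0.344
combo	rs34785252 CC:GG	or	0.306
combo	rs34785252 CA/AA:GG	or	0.283
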