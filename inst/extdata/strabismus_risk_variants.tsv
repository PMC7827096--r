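gene	pLI	hgvs_c	protein	consequence	allele_freq	population	sift	polyphen
ARID1B	0.999	c.3152C>A	p.T1051N	missense_variant	8.804e-6	EUR	deleterious	benign
ARNT2	0.959	c.179C>A	p.P60H	missense_variant		NA	deleterious	probably_damaging
COL4A1	0.999	c.3712C>T	p.R1238C	missense_variant	4.20e-5	EUR	deleterious	probably_damaging
FBN2	0.999	c.7690C>G	p.Q2564E	missense_variant	7.926e-5	EUR	deleterious	probably_damaging
LRRTM1	0.951	c.914C>T	p.S305F	missense_variant	1.761e-5	EUR	deleterious	probably_damaging
CTNNA1	0.970	c.347G>A	p.C116Y	missense_variant	2.637e-5	EUR	deleterious	probably_damaging
KCNH2	0.996	c.526C>T	p.R176W	missense_variant	6.557e-4	EUR	deleterious	probably_damaging
TTYH1	0.998	c.1145G>C	p.R382P	missense_variant		NA	tolerated	probably_damaging
ANO1	0.993	c.1031C>T	p.P344L	missense_variant		NA	deleterious	probably_damaging
CELSR1	0.999	c.7312C>T	p.R2438W	missense_variant	6.408e-5	EUR	deleterious	probably_damaging
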