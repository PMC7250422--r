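arm	offset	ref	alt	haplotype
left	47	G	C	2
left	214	G	C	2
left	378	G	A	2
left	521	A	G	1
left	562	T	C	2
left	703	T	C	2
left	886	G	C	2
right	160	T	C	1
right	622	T	C	2
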