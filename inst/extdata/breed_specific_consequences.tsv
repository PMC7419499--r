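category	level	lori_bakhtiari	zel
impact	HIGH	1	7
impact	MODERATE	209	1054
impact	LOW	501	2791
impact	MODIFIER	2063	6618
type	downstream_gene	1227	3660
type	upstream_gene	144	581
type	intergenic	212	617
type	three_prime_utr	155	472
type	five_prime_utr	13	52
type	intron	310	1208
type	synonymous	495	2776
type	missense	209	1054
type	stop_gained	1	3
type	stop_lost	0	1
type	stop_retained	0	1
type	start_lost	0	3
type	other	8	42
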