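metric	value
confident_snps	120049
known_snps	112344
lori_bakhtiari_snps	68089
zel_snps	93846
lori_bakhtiari_common	30550
zel_common	42906
lori_bakhtiari_specific	2774
zel_specific	10470
lori_bakhtiari_in_qtl	724
zel_in_qtl	2905
lori_bakhtiari_qtl_pairs	1155
zel_qtl_pairs	4379
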