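category	level	n
cases	total	217
site	colon	169
site	rectal	48
sex	male	118
sex	female	99
race	non_hispanic_white	161
race	hispanic	14
race	non_hispanic_black	8
race	unknown	34
phenotype	TP53_mutated	103
phenotype	KRAS_mutated	69
phenotype	BRAF_mutated	21
phenotype	CIMP_high	45
phenotype	MSI	29
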