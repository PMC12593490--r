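chromosome	length_bp	n_variants	bases_per_variant
HM01chromosome01	5516215	50521	109
HM01chromosome02	4999619	25960	192
HM01chromosome03	4517060	45393	99
HM01chromosome04	4177578	55723	74
HM01chromosome05	4102088	41022	99
HM01chromosome06	3364172	41508	81
HM01chromosome07	3318489	30705	108
HM01chromosome08	2643500	35713	74
HM01chromosome09	2421378	26604	91
HM01chromosome10	2260060	24311	92
HM01chromosome11	2188314	19619	111
HM01chromosome12	2080224	15831	131
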