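gene_id	length
GENE_A	400
GENE_B	480
GENE_C	510
GENE_D	560
GENE_E	590
GENE_F	620
GENE_G	660
GENE_H	14200
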