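patient_id	gene_id	count
PAT1	GENE_H	1
PAT1	GENE_A	2
PAT1	GENE_F	2
PAT1	GENE_G	1
PAT2	GENE_H	1
PAT2	GENE_A	2
PAT2	GENE_F	2
PAT3	GENE_H	1
PAT3	GENE_A	2
PAT3	GENE_C	2
PAT4	GENE_H	1
PAT4	GENE_A	2
PAT4	GENE_F	1
PAT4	GENE_D	2
PAT4	GENE_E	2
PAT5	GENE_H	1
PAT5	GENE_A	2
PAT5	GENE_C	2
PAT5	GENE_G	2
PAT6	GENE_H	1
PAT6	GENE_F	1
PAT6	GENE_B	1
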