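variant_id	donor_id	assay	cell_type	ref_count	alt_count
v1	d1	TF	neutrophil	9	1
v1	d2	TF	neutrophil	12	3
v2	d1	TF	neutrophil	10	0
v2	d2	TF	neutrophil	8	3
v3	d1	TF	neutrophil	5	4
v3	d2	TF	neutrophil	6	4
v4	d1	TF	neutrophil	15	15
v4	d2	TF	neutrophil	14	16
v5	d1	TF	neutrophil	3	27
v5	d2	TF	neutrophil	4	26
v6	d1	TF	neutrophil	30	70
v6	d2	TF	neutrophil	70	30
v7	d1	TF	neutrophil	20	5
v7	d1	TF	monocyte	18	6
v8	d1	TF	neutrophil	20	10
v9	d1	PCHiC	neutrophil	199	1
v9	d2	PCHiC	neutrophil	150	100
v10	d1	PCHiC	neutrophil	39	61
v10	d2	PCHiC	neutrophil	35	65
v11	d1	PCHiC	neutrophil	50	50
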