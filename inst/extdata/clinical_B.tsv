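SAMPLE_ID	OS_MONTHS	OS_STATUS
TCGA-B-01	20.59	DECEASED
TCGA-B-02	7.79	DECEASED
TCGA-B-03	24	DECEASED
TCGA-B-04	11.01	DECEASED
TCGA-B-05	21.06	DECEASED
TCGA-B-06	11.22	DECEASED
TCGA-B-07	18.62	LIVING
TCGA-B-08	2.66	DECEASED
TCGA-B-09	36.31	DECEASED
TCGA-B-10	0.52	DECEASED
TCGA-B-11	19.68	LIVING
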