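SAMPLE_ID	OS_MONTHS	OS_STATUS
TCGA-A-01	1.66	DECEASED
TCGA-A-02	39.43	DECEASED
TCGA-A-03	41.62	DECEASED
TCGA-A-04	19.99	DECEASED
TCGA-A-05	13.59	LIVING
TCGA-A-06	63.39	DECEASED
TCGA-A-07	18.54	LIVING
TCGA-A-08	103.05	LIVING
TCGA-A-09	5.41	DECEASED
TCGA-A-10	1.59	LIVING
TCGA-A-11	23.16	DECEASED
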