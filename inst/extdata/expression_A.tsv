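Hugo_Symbol	TCGA-A-01	TCGA-A-02	TCGA-A-03	TCGA-A-04	TCGA-A-05	TCGA-A-06	TCGA-A-07	TCGA-A-08	TCGA-A-09	TCGA-A-10	TCGA-A-11	TCGA-A-12
AKT1	10.742	7.788	10.61	9.272	7.387	7.139	8.911	4.566	8.412	8.866	8.644	8.553
BRCA1	6.871	11.023	12.573	7.431	4.437	7.485	9.41	6.431	7.278	6.377	6.432	9.359
EGFR	8.726	7.811	5.222	2.687	7.656	4.474	10.07	6.298	9.516	10.888	11.151	8.18
MAPK1	9.266	12.037	7.442	3.119	10.429	8.92	6.782	3.172	6.547	7.137	9.286	2.014
TP53	8.809	7.875	7.733	10.64	11.79	6.72	9.01	8.072	5.263	9.311	8.18	8.57
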