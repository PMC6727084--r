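Hugo_Symbol	TCGA-B-01	TCGA-B-02	TCGA-B-03	TCGA-B-04	TCGA-B-05	TCGA-B-06	TCGA-B-07	TCGA-B-08	TCGA-B-09	TCGA-B-10	TCGA-B-11	TCGA-B-12
BRCA1	7.266	10.605	5.914	9.162	11.025	9.224	10.784	6.278	10.402	8.211	7.95	7.235
EGFR	8.37	8.672	7.82	9.536	8.516	7.566	7.048	5.737	10.09	7.155	8.216	6.975
KRAS	9.164	10.077	9.247	8.928	8.177	7.634	9.301	5.082	5.994	7.755	7.029	13.404
MAPK1	10.799	9.841	6.093	6.228	7.758	9.867	10.782	8.16	11.697	8.376	6.992	5.276
TP53	6.545	9.442	6.914	5.8	5.611	9.644	5.778	9.306	6.666	8.238	4.678	8.275
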