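promoter	gene_id	min_rank	max_rank	median_rank	utr_length	tested_length	description
P1	AFLA_090780	1	32	5	1309	1029	Translation elongation factor EF-1 alpha subunit (TEF1)
NA	AFLA_064900	1	9772	12	525	NA	Hypothetical protein
P2	AFLA_025100	3	886	12	1792	1024	Glyceraldehyde 3-phosphate dehydrogenase (GpdA)
P3	AFLA_014570	1	313	12	3461	1024	Conserved hypothetical protein
NA	AFLA_050690	3	174	16	314	NA	Mitochondrial ADP/ATP carrier protein
P4	AFLA_113120	5	177	18	6093	1024	GPI-anchored cell wall organization protein (Ecm33)
NA	AFLA_048690	1	1022	18	2918	NA	Alcohol dehydrogenase, putative
NA	AFLA_063260	1	11577	19	409	NA	Conserved hypothetical protein
NA	AFLA_083050	1	98	21	345	NA	40S ribosomal protein S25
P5	AFLA_052860	1	555	27	967	967	Chaperone/heat shock protein (Hsp12)
NA	AFLA_047870	7	128	34	41	NA	40S ribosomal protein S16
NA	AFLA_006300	8	570	34	2864	NA	Nucleoside diphosphate kinase
P6	AFLA_030930	6	140	34	2864	1024	Fructose-bisphosphate aldolase, class II
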