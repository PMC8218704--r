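patient_id	assay_id	sample_type	biofluid_volume	vaf_printed_percent	mutant_droplets	wt_droplets	cfdna_mutant_ng_ml	cfdna_wt_ng_ml
013-T	H3F3A-K27M	plasma	2.7	2.451	10	398	0.028	1.131
045-T	TP53-R282W	CSF	5	49.343	3945	4050	271.913	279.585
045-T	TP53-R282W	plasma	5	0.118	3	2540	0.021	18.313
054-T	H3F3A-G34R	plasma	5	0.468	2	425	0.007	1.561
106-T	IDH1-R132H	plasma	3.5	0.335	11	3272	0.029	8.844
120-T	H3F3A-G34R	plasma	3	1.143	2	173	0.005	0.422
131-T	H3F3A-K27M	cyst	38.5	42.68	10944	14698	367.594	541.671
131-T	H3F3A-K27M	plasma	2	0.85	3	350	0.009	1.048
15-3381	H3F3A-K27M	CSF	1	3.646	7	185	0.044	1.177
16120B	PIK3CA-E542K	serum	2	0.072	7	9674	0.291	472.795
ICR-B134	H3F3A-K27M	serum	1.3	0.39	2	511	0.015	3.934
ICR-B276	PIK3CA-H1047R	plasma	2	0.116	2	1727	0.006	5.098
ICR-CXJ-026	TP53-C238Y	CSF	2.5	2.073	4	189	0.013	0.633
ICR-CXJ-028	ACVR1-G328V	CSF	1.8	35.737	446	802	1.472	2.662
I-16-3200	H3F3A-K27M	CSF	0.7	0.051	3	5916	0.071	159.274
I-16-855	H3F3A-K27M	CSF	1.5	1.149	9	774	0.054	4.703
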