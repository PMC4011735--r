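gene_id	timepoint	dge_log2_ratio	qpcr_display	qpcr_sd	significant
Bm_nscaf2674_064	1h	9.32	19.56	2.27	TRUE
Bm_nscaf2674_063	1h	5.13	10.4	1.70	TRUE
Bm_nscaf2838_045	1h	6.77	1.21	0.09	FALSE
Bm_nscaf2818_064	4h	5.46	1.95	0.132	TRUE
Bm_nscaf2767_133	4h	9.36	1.50	0.23	TRUE
Bm_nscaf2795_018	8h	-2.94	-9.04	1.50	TRUE
Bm_scaffold769_2	8h	8.90	2.78	0.22	TRUE
Bm_nscaf2983_049	8h	9.98	7.95	0.84	TRUE
Bm_nscaf3013_07	8h	10.12	3.75	0.45	TRUE
Bm_nscaf2847_194	8h	-3.67	-2.97	0.14	TRUE
Bm_nscaf3087_01	8h	-8.69	-5.64	0.66	TRUE
Bm_nscaf1108_005	12h	7.29	5.46	0.23	TRUE
Bm_scaffold721_3	12h	4.26	8.27	0.74	TRUE
Bm_nscaf3003_091	12h	8.07	4.52	0.56	TRUE
Bm_nscaf463_08	12h	9.27	17.3	2.6	TRUE
Bm_nscaf2818_106	24h	4.47	2.98	3.7	TRUE
Bm_nscaf2931_28	24h	3.14	1.07	0.11	FALSE
Bm_nscaf463_19	24h	-2.25	-1.55	0.13	TRUE
Bm_nscaf2818_106	24h	2.54	7.46	0.65	TRUE
Bm_nscaf3045_59	24h	-3.07	-6.43	0.63	TRUE
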