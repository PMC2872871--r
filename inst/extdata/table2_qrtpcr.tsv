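gene	region	microarray_ratio	qrtpcr_ratio	microarray_significant
Ptprr	nucleus_accumbens	2.22	2.28	TRUE
Ptprr	amygdala	2.47	2.71	TRUE
Ptprr	frontal_cortex	2.17	1.85	TRUE
Ptprr	hippocampus	2.42	2.77	TRUE
Ptprr	caudate_putamen	1.98	2.28	TRUE
Copg2_IT	nucleus_accumbens	-3.97	-2.45	TRUE
Copg2_IT	amygdala	-28.29	-1.73	TRUE
Copg2_IT	frontal_cortex	-31.36	-1.61	TRUE
Copg2_IT	hippocampus	-4.57	-2.12	TRUE
Copg2_IT	caudate_putamen	-20.13	-1.23	TRUE
Ppm1k	nucleus_accumbens	-2.05	1.30	TRUE
Ppm1k	amygdala	-1.74	-1.62	TRUE
Ppm1k	frontal_cortex	-2.79	-2.54	TRUE
Ppm1k	hippocampus	-1.86	-3.12	TRUE
Ppm1k	caudate_putamen	-2.39	-2.49	TRUE
Snx10	nucleus_accumbens	1.67	-1.16	TRUE
Snx10	amygdala	2.18	1.68	TRUE
Snx10	frontal_cortex	1.94	1.15	TRUE
Snx10	hippocampus	1.69	2.42	TRUE
Snx10	caudate_putamen	2.02	1.64	TRUE
Zfp212	nucleus_accumbens	1.30	1.54	TRUE
Zfp212	amygdala	1.22	-1.04	TRUE
Zfp212	frontal_cortex	1.21	1.19	TRUE
Zfp212	hippocampus	1.28	1.58	TRUE
Zfp212	caudate_putamen	1.43	1.86	TRUE
Akr1b1	nucleus_accumbens	1.22	1.13	TRUE
Akr1b1	amygdala	1.12	1.30	TRUE
Akr1b1	frontal_cortex	1.27	1.58	TRUE
Akr1b1	hippocampus	1.16	1.06	TRUE
Akr1b1	caudate_putamen	1.25	1.15	TRUE
Dgki	nucleus_accumbens	1.23	2.72	TRUE
Dgki	amygdala	1.13	-1.26	TRUE
Dgki	frontal_cortex	1.17	-2.97	TRUE
Dgki	hippocampus	1.26	1.11	TRUE
Dgki	caudate_putamen	1.25	-1.71	TRUE
Pdia4	nucleus_accumbens	1.24	1.57	TRUE
Pdia4	amygdala	1.34	-1.01	TRUE
Pdia4	frontal_cortex	1.14	1.05	FALSE
Pdia4	caudate_putamen	1.36	-1.13	TRUE
Snca	frontal_cortex	-1.11	-1.22	TRUE
Snca	hippocampus	1.07	1.05	FALSE
Snca	caudate_putamen	-1.12	-1.09	TRUE
Npy	frontal_cortex	-1.11	1.01	FALSE
Npy	caudate_putamen	-1.08	-1.20	FALSE
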