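condition	parameter	mean	sem	n	code
control	growth_rate	25.9	1.8	54	
control	shortening_rate	31.1	2.6	54	
control	growth_length	1.87	0.16	54	
control	shortening_length	1.59	0.08	54	
control	pct_time_G	28.7	2.1	54	
control	pct_time_S	17.3	1.4	54	
control	pct_time_P	53.6	2.7	54	
control	cat_per_min	4.65	0.42	54	
control	res_per_min	18.91	0.89	54	
control	cat_per_um	0.75	0.08	54	
control	res_per_um	0.93	0.13	54	
control	dynamicity	14.4	1.73	54	
1uM	growth_rate	26.7	1.2	44	
1uM	shortening_rate	32.7	2.0	44	
1uM	growth_length	1.50	0.06	44	C
1uM	shortening_length	1.71	0.07	44	
1uM	pct_time_G	29.2	1.7	44	
1uM	pct_time_S	22.9	1.6	44	B
1uM	pct_time_P	47.9	2.8	44	
1uM	cat_per_min	6.49	0.52	44	B
1uM	res_per_min	20.08	0.71	44	
1uM	cat_per_um	0.63	0.04	44	
1uM	res_per_um	0.74	0.07	44	
1uM	dynamicity	16.01	1.37	44	
5uM	growth_rate	26.9	1.3	44	
5uM	shortening_rate	31.4	1.9	44	
5uM	growth_length	1.47	0.06	44	C
5uM	shortening_length	1.52	0.05	44	
5uM	pct_time_G	24.2	1.5	44	
5uM	pct_time_S	20.0	1.2	44	
5uM	pct_time_P	55.8	2.2	44	
5uM	cat_per_min	5.01	0.27	44	
5uM	res_per_min	20.43	0.55	44	
5uM	cat_per_um	0.77	0.10	44	
5uM	res_per_um	0.95	0.15	44	
5uM	dynamicity	12.66	0.86	44	
25uM	growth_rate	20.3	0.7	68	B
25uM	shortening_rate	24.5	1.3	68	B
25uM	growth_length	1.12	0.04	68	A
25uM	shortening_length	1.19	0.04	68	A
25uM	pct_time_G	20.5	1.4	68	A
25uM	pct_time_S	17.7	1.0	68	
25uM	pct_time_P	61.9	2.0	68	B
25uM	cat_per_min	4.81	0.31	68	
25uM	res_per_min	20.24	0.59	68	
25uM	cat_per_um	1.07	0.11	68	C
25uM	res_per_um	1.58	0.19	68	B
25uM	dynamicity	8.65	0.68	68	A
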