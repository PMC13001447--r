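context	site_class	alpha	alpha_lower	alpha_upper	beta	beta_lower	beta_upper
CG	single_site	1.62e-5	1.18e-5	2.09e-5	8.55e-5	6.25e-5	11.11e-5
CHG	single_site	1.54e-5	1.07e-5	2.06e-5	8.19e-5	5.70e-5	10.94e-5
CHH	single_site	2.17e-5	1.59e-5	2.83e-5	7.18e-5	5.26e-5	9.35e-5
CG	dmr_bin	1.72e-5	1.37e-5	2.05e-5	8.79e-5	6.99e-5	10.50e-5
CHG	dmr_bin	0.79e-5	0.53e-5	1.06e-5	5.66e-5	3.79e-5	7.58e-5
CHH	dmr_bin	3.01e-5	2.24e-5	3.75e-5	7.19e-5	5.35e-5	8.94e-5
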