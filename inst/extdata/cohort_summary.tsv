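variable	dispersion_kind	mean_EOS	disp_EOS	n_EOS	mean_SB	disp_SB	n_SB	mean_HC	disp_HC	n_HC
age	sem	18.37	0.63	27	19.92	0.67	24	19.73	0.47	48
education	sem	10.63	0.5	27	11.5	0.5	24	12.5	0.37	48
acc_2back	sd	0.70	0.14	27	0.77	0.18	24	0.84	0.12	48
acc_0back	sd	0.88	0.16	27	0.87	0.20	24	0.94	0.09	48
fd_interp_count	sd	7.88	11.09	27	8.33	11.48	24	9.28	13.9	48
sigma	sem	1.421	0.031	27	1.27	0.033	24	1.3	0.023	48
gamma	sem	1.52	0.032	27	1.37	0.034	24	1.39	0.024	48
lambda	sem	1.06	0.004	27	1.073	0.005	24	1.065	0.0033	48
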