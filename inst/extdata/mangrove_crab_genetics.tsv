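species	n_seq	n_hap	seg_sites	hap_div	hap_div_se	theta_pi_pct	theta_w_pct	gammast	tajima_d	fu_fs	r2	raggedness	tau_dem	tau_dem_lo	tau_dem_hi	tau_sp	tau_sp_lo	tau_sp_hi
Uca_inversa	120	26	18	0.78	0.03	0.29	0.54	0.056	-1.3	-20.03	0.16	0.02	2.31	0.62	3.96	2.11	0.63	3.29
Uca_occidentalis	421	18	17	0.19	0.03	0.03	0.41	0.029	-2.23	-33.96	0.16	0.2	3.0	0.40	3.0	0.08	0.06	0.87
Uca_hesperiae	125	28	23	0.80	0.02	0.25	0.68	0.040	-1.82	-25.87	0.15	0.05	1.72	1.43	2.10	1.72	1.02	2.12
Perisesarma_guttatum	224	60	47	0.85	0.02	0.42	1.21	0.019	-1.89	-26.36	0.16	0.02	3.95	1.45	6.45	3.15	1.19	5.04
Neosarmatium_africanum	147	32	31	0.82	0.02	0.46	0.9	0.039	-1.48	-19.82	0.04	0.05	4.59	1.15	8.11	2.53	0.71	6.39
Scylla_serrata	190	42	45	0.62	0.40	0.26	1.40	0.034	-2.43	-28.69	0.16	0.05	2.67	0.02	5.03	1.81	0.43	3.62
Cardisoma_carnifex	78	11	9	0.63	0.03	0.12	0.29	0.046	-1.48	-7.32	0.16	0.16	0.93	0.64	1.38	0.93	0.48	1.28
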