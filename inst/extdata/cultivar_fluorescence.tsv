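cultivar	variety	fv_fm	fv_fm_se	phi_psii	phi_psii_se	etr	etr_se	abs	abs_se	chlorophyll	chlorophyll_se	pri	pri_se
Domari	endive	0.793	0.001	0.405	0.004	55.73	0.53	0.746	0.006	19.87	0.96	0.043	0.001
Myrna	endive	0.807	0.001	0.375	0.003	49.42	0.47	0.715	0.002	17.25	1.98	0.038	0.001
Flester	escarole	0.828	0.001	0.375	0.003	46.64	0.47	0.675	0.009	14.51	1.01	0.033	0.001
Confiance	escarole	0.781	0.001	0.419	0.005	60.16	0.76	0.778	0.002	23.57	0.58	0.042	0.001
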