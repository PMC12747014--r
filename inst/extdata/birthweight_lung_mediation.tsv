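exposure	mediator	outcome	beta1	se1	beta2	se2	beta0	se0	reported_proportion	reported_ci_low	reported_ci_high
Birth weight	s_Ruminococcus_obeum	FVC	0.276	0.081	0.203	0.029	0.202	0.026	27.85	8.65	47.05
Birth weight	s_Subdoligranulum_unclassified	FVC	0.201	0.084	0.203	0.030	0.202	0.026	20.16	1.89	38.42
Birth weight	g_Blautia	FVC	0.194	0.075	0.206	0.028	0.202	0.026	19.84	3.08	36.59
Birth weight	PWY.7237..myo...chiro..and.scillo.inositol.degradation	FVC	0.184	0.072	0.203	0.029	0.202	0.026	18.53	2.65	34.41
Birth weight	P441.PWY..superpathway.of.N.acetylneuraminate.degradation	FVC	0.171	0.074	0.209	0.028	0.202	0.026	17.71	1.36	34.06
Birth weight	s_Ruminococcus_obeum	FEV1	0.276	0.081	0.179	0.026	0.171	0.024	28.91	8.69	49.13
Birth weight	g_Blautia	FEV1	0.194	0.075	0.177	0.025	0.171	0.024	20.17	2.93	37.41
Birth weight	s_Subdoligranulum_unclassified	FEV1	0.201	0.084	0.170	0.027	0.171	0.024	20.02	1.67	38.37
Birth weight	PWY.7237..myo...chiro..and.scillo.inositol.degradation	FEV1	0.184	0.072	0.174	0.026	0.171	0.024	18.76	2.48	35.04
Birth weight	P441.PWY..superpathway.of.N.acetylneuraminate.degradation	FEV1	0.171	0.074	0.174	0.025	0.171	0.024	17.42	1.12	33.71
Birth weight	s_Ruminococcus_obeum	Lung volume	0.276	0.081	0.259	0.049	0.267	0.046	26.89	6.32	47.46
Birth weight	s_Subdoligranulum_unclassified	Lung volume	0.201	0.084	0.259	0.051	0.267	0.046	19.52	0.66	38.37
Birth weight	g_Blautia	Lung volume	0.194	0.075	0.256	0.048	0.267	0.046	18.66	1.70	35.62
Birth weight	PWY.7237..myo...chiro..and.scillo.inositol.degradation	Lung volume	0.184	0.072	0.265	0.049	0.267	0.046	18.26	1.54	34.97
Birth weight	P441.PWY..superpathway.of.N.acetylneuraminate.degradation	Lung volume	0.171	0.074	0.270	0.048	0.267	0.046	17.34	0.42	34.26
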