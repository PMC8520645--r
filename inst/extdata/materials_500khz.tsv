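material	relative_permittivity	sigma	density	heat_capacity	thermal_conductivity	temp_coefficient
blood	4190	0.748	1050	3617	0.52	0
artery_wall	312	0.324	1102	3306	0.46	0.0205
connective_tissue	201	0.391	1027	2372	0.39	0.0205
insulator	4	1.25e-12	1010	1700	0.26	0
electrode_metal	1	1e9	7950	502	14	0
gel	201	0.391	1030	4186	0.60	0.0205
ambient	1	0	0	0	0	0
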