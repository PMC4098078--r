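name	x_mm	y_mm	z_mm	radius_mm
L44	-57	6	27	5
R44	54	6	33	5
MCC	-9	12	42	5
L_IPS	-36	-39	48	5
R_IPS	42	-33	45	5
L_HIP	-27	-9	-24	5
L_TP	-48	9	-18	5
L_pSTS	-54	-42	6	5
L_CAUD	-9	3	15	5
R_CAUD	15	21	15	5
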