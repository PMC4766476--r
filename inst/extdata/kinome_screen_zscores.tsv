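gene_id	dsrna_id	z	control_role
CncC	CncC_ds1	-4.52	pathway-positive
MafS	MafS_ds1	-3.61	pathway-positive
Keap1	Keap1_ds1	0.7	pathway-negative
Cdk12	Cdk12_ds1	-25.1	none
Cdk12	Cdk12_ds2	-28.27	none
Cdk12	Cdk12_ds3	-39.64	none
fray	fray_ds1	-3.4	none
fray	fray_ds2	-3.82	none
fray	fray_ds3	-0.19	none
Madm	Madm_ds1	-1.92	none
Madm	Madm_ds2	-2.86	none
Madm	Madm_ds3	-3.29	none
Psi	Psi_ds1	-0.93	none
Psi	Psi_ds2	-2.84	none
Psi	Psi_ds3	-3.02	none
CK2a	CK2a_ds1	-1.93	none
CK2a	CK2a_ds2	-1.94	none
CK2a	CK2a_ds3	-1.95	none
Fs(1)h	Fs(1)h_ds1	1.96	none
Fs(1)h	Fs(1)h_ds2	1.9	none
Fs(1)h	Fs(1)h_ds3	1.6	none
GSK-3	GSK-3_ds1	2.09	none
GSK-3	GSK-3_ds2	1.88	none
GSK-3	GSK-3_ds3	1.19	none
Nipped-A	Nipped-A_ds1	1.27	none
Nipped-A	Nipped-A_ds2	1.81	none
Nipped-A	Nipped-A_ds3	1.81	none
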