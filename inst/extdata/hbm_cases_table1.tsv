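id	sum_z	ls_z	hip_z	age	cohort	dna_available	genotyped
HBM1	6.1	3.4	2.7	51	BARCOS	FALSE	FALSE
HBM2	4.6	3.0	1.6	57	BARCOS	TRUE	TRUE
HBM3	4.9	2.5	2.4	55	BARCOS	TRUE	TRUE
HBM4	4.5	2.5	2.0	62	BARCOS	TRUE	TRUE
HBM5	4.5	2.4	2.1	66	BARCOS	TRUE	TRUE
HBM6	5.1	2.6	2.5	52	BARCOS	TRUE	TRUE
HBM7	4.6	2.5	2.1	61	BARCOS	TRUE	TRUE
HBM8	7.9	4.0	3.9	55	BARCOS	FALSE	FALSE
HBM9	7.0	4.6	2.4	66	BARCOS	TRUE	TRUE
HBM10	5.1	2.8	2.3	75	BARCOS	TRUE	TRUE
HBM11	6.8	3.8	3.0	55	HSANTPAU	FALSE	FALSE
HBM12	6.4	3.8	2.6	59	CETIR	TRUE	TRUE
HBM13	5.2	2.6	2.6	67	CETIR	TRUE	TRUE
HBM14	6.0	3.7	2.3	64	CETIR	TRUE	FALSE
HBM15	4.5	2.4	2.1	54	CETIR	TRUE	TRUE
HBM16	5.3	3.6	1.7	77	HESP	TRUE	FALSE
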