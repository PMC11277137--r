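molecule	species	n_o	N	Pp_al_ref	p_al_ref	mean_Pp_al_ref
rprotein_L18	HS	13	552	7.4	3.7	8.3
rprotein_L18	SC	16	557	10	5	8.3
rprotein_L18	Mv	12	581	6	3	8.3
rprotein_L18	Mmi	16	578	9.8	4.9	8.3
rRNA_5S	HS	2	117	2	1	10.6
rRNA_5S	SC	2	117	2	1	10.6
rRNA_5S	Mv	14	112	26.2	13.1	10.6
rRNA_5S	Mmi	7	111	12.2	6.1	10.6
Gly_tRNA_ligase	HS	36	2015	8.8	4.4	11.05
Gly_tRNA_ligase	SC	45	2000	13	6.5	11.05
Gly_tRNA_ligase	Mv	37	1751	11	5.5	11.05
Gly_tRNA_ligase	Mmi	37	1721	11.4	5.7	11.05
DNA_polymerase	HS	21	1286	5.8	2.9	12.43
DNA_polymerase	SC	36	1895	9.5	4.75	12.43
DNA_polymerase	Mv	59	2472	16.2	8.1	12.43
DNA_polymerase	Mmi	30	749	18.2	9.1	12.43
Translocase	HS	42	3178	5.4	2.7	14.5
Translocase	SC	130	4856	26.8	13.4	14.5
Translocase	Mv	76	2969	19.6	9.8	14.5
Translocase	Mmi	22	1325	6	3	14.5
ATPase	HS	29	1755	7	3.5	15.3
ATPase	SC	42	1850	12.8	6.4	15.3
ATPase	Mv	21	608	13.6	6.8	15.3
ATPase	Mmi	97	2978	27.8	13.9	15.3
Helicase	HS	48	2255	12.6	6.3	18.15
Helicase	SC	95	3029	26.6	13.3	18.15
Helicase	Mv	57	2465	15.2	7.6	18.15
Helicase	Mmi	60	2236	18.2	9.1	18.15
tRNA_Gly	HS	18	22	81	40.5	84.4
tRNA_Gly	SC	17	22	76.4	38.2	84.4
tRNA_Gly	Mv	19	22	85.5	42.8	84.4
tRNA_Gly	Mmi	21	22	94.6	47.3	84.4
AL	AL	22	22	100	50	100
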