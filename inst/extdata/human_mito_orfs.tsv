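transcript_id	gene	start	end	stop_completed_by_polyA
MT-ND1	ND1	0	956	TRUE
MT-ND2	ND2	0	1042	TRUE
MT-CO1	COX1	0	1542	FALSE
MT-CO2	COX2	0	684	FALSE
MT-ATP8_ATP6	ATP8	0	207	FALSE
MT-ATP8_ATP6	ATP6	161	842	FALSE
MT-CO3	COX3	0	784	TRUE
MT-ND3	ND3	0	346	TRUE
MT-ND4L_ND4	ND4L	0	297	FALSE
MT-ND4L_ND4	ND4	290	1668	TRUE
MT-ND5	ND5	0	1812	FALSE
MT-ND6	ND6	0	525	FALSE
MT-CYB	CYB	0	1141	TRUE
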