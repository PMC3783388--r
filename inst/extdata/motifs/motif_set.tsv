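group	domain_class	seed_file
Ngaro1	RT	Ngaro1_RT.faa
Ngaro1	RH	Ngaro1_RH.faa
Ngaro1	YR	Ngaro1_YR.faa
Ngaro2	RT	Ngaro2_RT.faa
Ngaro2	RH	Ngaro2_RH.faa
Ngaro2	YR	Ngaro2_YR.faa
Ngaro3	RT	Ngaro3_RT.faa
Ngaro3	RH	Ngaro3_RH.faa
Ngaro3	YR	Ngaro3_YR.faa
Ngaro4	RT	Ngaro4_RT.faa
Ngaro4	RH	Ngaro4_RH.faa
Ngaro4	YR	Ngaro4_YR.faa
DIRS_A	RT	DIRS_A_RT.faa
DIRS_A	RH	DIRS_A_RH.faa
DIRS_A	YR	DIRS_A_YR.faa
DIRS_B	RT	DIRS_B_RT.faa
DIRS_B	RH	DIRS_B_RH.faa
DIRS_B	YR	DIRS_B_YR.faa
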