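name	domain_class	affinity	seed_file
RVT_1	RT	generic	RVT_1.faa
RT_DIRS1	RT	DIRS-specific	RT_DIRS1.faa
RT_Ngaro	RT	Ngaro-like	RT_Ngaro.faa
Rnase_H	RH	generic	Rnase_H.faa
RNase_HI_RT_DIRS1	RH	DIRS-specific	RNase_HI_RT_DIRS1.faa
RH_Ngaro	RH	Ngaro-like	RH_Ngaro.faa
Phage_integrase	YR	generic	Phage_integrase.faa
Dam	MT	DIRS-specific	Dam.faa
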