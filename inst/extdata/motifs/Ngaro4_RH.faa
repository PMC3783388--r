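>Ngaro4_RH_m0
AFLIPHSFRGRRSSVRTHYEHAMCQTQRHK
>Ngaro4_RH_m1
AFSIPHSFRGRRSSVRTHYEHAMCQTQRHK
>Ngaro4_RH_m2
AFLIMHSFRGRRSSVRTHYEHAMCQTQRHK
>Ngaro4_RH_m3
AFLQPHSFRGRRSSVRTHYEHAMCQTQRHK
>Ngaro4_RH_m4
FFLIPHSFRGRRSSVRTHYEHAMCQTQRHK
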