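>Ngaro1_RT_m0
FHISQYGMEGPMHTRRAVFWHTYKCSVYIA
>Ngaro1_RT_m1
FHISQYGMEGPMHTRRAVFWHNYKCSVYIA
>Ngaro1_RT_m2
FHISQYGMEGPMHMRRAVFWHTYKCSVYIA
>Ngaro1_RT_m3
FHISQYGMEFPMHTRRAVFWHTYKCSVYIA
>Ngaro1_RT_m4
FHISQYGMEGFMHTRRAVFWHTYKCSVYIA
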