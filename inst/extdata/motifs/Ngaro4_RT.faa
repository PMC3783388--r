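>Ngaro4_RT_m0
FHISQYGMENPMHTRRAVFWHTYKCSVYIA
>Ngaro4_RT_m1
FHISQYGMENPMHTRRAVFSHTYKCSVYIA
>Ngaro4_RT_m2
FHISQYGMENPMHQRRAVFWHTYKCSVYIA
>Ngaro4_RT_m3
FHISQYGMEPPMHTRRAVFWHTYKCSVYIA
>Ngaro4_RT_m4
FHISLYGMENPMHTRRAVFWHTYKCSVYIA
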