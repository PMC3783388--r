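>Ngaro2_RT_m0
FHISIYGMEGPMHTRRAVFTHTYKCSVYIA
>Ngaro2_RT_m1
YHISIYGMEGPMHTRRAVFTHTYKCSVYIA
>Ngaro2_RT_m2
FHISIYGMEGPMHTRRAVFYHTYKCSVYIA
>Ngaro2_RT_m3
FHISIYGMEGPMHTRRAVFTHTYKCSVYIE
>Ngaro2_RT_m4
FHISIYGMEGPMHTRRAVGTHTYKCSVYIA
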