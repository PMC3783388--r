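>Ngaro2_RH_m0
EFEIPMSFRPWRSSVRTHYFHAMCGTQEYK
>Ngaro2_RH_m1
EFSIPMSFRPWRSSVRTHYFHAMCGTQEYK
>Ngaro2_RH_m2
EFEIWMSFRPWRSSVRTHYFHAMCGTQEYK
>Ngaro2_RH_m3
EFEIPMSFRPWRPSVRTHYFHAMCGTQEYK
>Ngaro2_RH_m4
EFEIPMSFRPWRSSVRTHYFHAMCGTQEYF
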