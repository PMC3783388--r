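>Ngaro3_RT_m0
FHISLYGMEGPMETRREVFQHTYKCHFYIA
>Ngaro3_RT_m1
FHISSYGMEGPMETRREVFQHTYKCHFYIA
>Ngaro3_RT_m2
FHISLYGMEGPMETRREVFQHTYKRHFYIA
>Ngaro3_RT_m3
FHISLYGMEQPMETRREVFQHTYKCHFYIA
>Ngaro3_RT_m4
FHISLYGMEGPMETRREVFQHTYKCHMYIA
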