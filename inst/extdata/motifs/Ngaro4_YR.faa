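>Ngaro4_YR_m0
DNVNAYYRCPWWCRHTNEGAYRFHMFQIYL
>Ngaro4_YR_m1
DNVNAYYRCPWWCRHTNEGAYRFHMFQIYF
>Ngaro4_YR_m2
RNVNAYYRCPWWCRHTNEGAYRFHMFQIYL
>Ngaro4_YR_m3
DNVNAYYDCPWWCRHTNEGAYRFHMFQIYL
>Ngaro4_YR_m4
DNVNAYYRCPWWCRHTNEGAYRFSMFQIYL
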