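>Ngaro2_YR_m0
DVVNSYQRCPWWCAHTQAVAYRKHIFQGKL
>Ngaro2_YR_m1
DVVNSYQRCPWWCAHTHAVAYRKHIFQGKL
>Ngaro2_YR_m2
DVVNSQQRCPWWCAHTQAVAYRKHIFQGKL
>Ngaro2_YR_m3
DVVNSYQRCPWWCAHTQAVAYRAHIFQGKL
>Ngaro2_YR_m4
DVVNSYQRCPWWCAMTQAVAYRKHIFQGKL
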