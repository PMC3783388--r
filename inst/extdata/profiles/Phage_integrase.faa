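>DIRS_A_YR
DTYASQGRPRGWENAHQRPPWWCEFTKMAAGLFHMFYWKLSTSAMVAPQCLTHRQKEMSW
>DIRS_B_YR
DTTASQGSIRGNEHAHQRPPWWFAFTQMAANIFHMFYGKLSTSEMVTPQCLTHRQMEMSW
>Ngaro1_YR
DMSALQRQPRDNVNAYYRCPWWCRHTPEGAYRFHMFQIYLSTSAHPTPKCLKERQMCFVW
>Ngaro2_YR
KMSALQGQPRDVVNSYQRCPWWCAHTQAVAYRKHIFQGKLSTSAHPTPKCLKERQMKFVW
>Ngaro3_YR
DMSALQGQPRDNVNSYQRCPMWWAHTQEGAYRFHMFKGKLSTSAHPTPICLWEVQMCTVW
>Ngaro4_YR
DMSYLQRQPRDNVNAYYRCPWWCRHTNEGAYRFHMFQIYLSTSAHPTPPCLKEDQFCFVW
>var1_YR
DTYASQGRPRGWENAHQRPPWWCEFTKMAAGLFHMFYWKLSFSAMVAPQCLTWRQKEMSW
>var2_YR
DTTASQGSIRGNLHAHQRPPWWFAFTQMVANIFHMFYGKLSTSEMVTPQCLTHRQMEMSW
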