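>Ngaro1_YR_m0
DNVNAYYRCPWWCRHTPEGAYRFHMFQIYL
>Ngaro1_YR_m1
DNVNAYYRCPWWCRHTPEGAYRFHMFQIPL
>Ngaro1_YR_m2
DNKNAYYRCPWWCRHTPEGAYRFHMFQIYL
>Ngaro1_YR_m3
DNVNAYYRCPWWCRHTPEGAYRFHMFQISL
>Ngaro1_YR_m4
DNVNAYYRCPWWCRHTPEGAYRFRMFQIYL
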