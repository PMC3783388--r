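>Ngaro3_YR_m0
DNVNSYQRCPMWWAHTQEGAYRFHMFKGKL
>Ngaro3_YR_m1
VNVNSYQRCPMWWAHTQEGAYRFHMFKGKL
>Ngaro3_YR_m2
DNVNSYQRCPMWWAHTQEGAYRDHMFKGKL
>Ngaro3_YR_m3
DNVNSYQRCPMWWAHTQEPAYRFHMFKGKL
>Ngaro3_YR_m4
DNVNSYQRCPMWWAHTQEGHYRFHMFKGKL
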