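>DIRS_B_YR_m0
GNEHAHQRPPWWFAFTQMAANIFHMFYGKL
>DIRS_B_YR_m1
GNEHAHQRPPWWFAFTQMAANIFEMFYGKL
>DIRS_B_YR_m2
GNEHAHQRPPWWFAFTQMAANIFHMDYGKL
>DIRS_B_YR_m3
GTEHAHQRPPWWFAFTQMAANIFHMFYGKL
>DIRS_B_YR_m4
GNEHAHQRPPWWFIFTQMAANIFHMFYGKL
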