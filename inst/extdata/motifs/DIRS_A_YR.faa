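>DIRS_A_YR_m0
GWENAHQRPPWWCEFTKMAAGLFHMFYWKL
>DIRS_A_YR_m1
GWENAHQRPPWWCEFTKMAAELFHMFYWKL
>DIRS_A_YR_m2
GWENAHQRPPWWCTFTKMAAGLFHMFYWKL
>DIRS_A_YR_m3
GWENAHQRPPWWCEFTKMAAGLRHMFYWKL
>DIRS_A_YR_m4
GWENAHQRPPWWCEFTKMASGLFHMFYWKL
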