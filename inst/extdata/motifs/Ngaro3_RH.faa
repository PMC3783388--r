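>Ngaro3_RH_m0
SFEIIHSFKPLFCSVRTHYQHAMCGTQEYK
>Ngaro3_RH_m1
SFEIIHSFKPLFCSVRTHYQHAVCGTQEYK
>Ngaro3_RH_m2
SFEIIHSFKPLFCSIRTHYQHAMCGTQEYK
>Ngaro3_RH_m3
SFEIIHSFKPLFCSVRTHYQHAMWGTQEYK
>Ngaro3_RH_m4
SFEMIHSFKPLFCSVRTHYQHAMCGTQEYK
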