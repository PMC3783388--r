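>DIRS_A_RT_m0
QHASLYRMEFPTHTINRVFWITYKCSWYPQ
>DIRS_A_RT_m1
QHASLFRMEFPTHTINRVFWITYKCSWYPQ
>DIRS_A_RT_m2
THASLYRMEFPTHTINRVFWITYKCSWYPQ
>DIRS_A_RT_m3
QHASLYRMEFQTHTINRVFWITYKCSWYPQ
>DIRS_A_RT_m4
QHASLYRMEFPNHTINRVFWITYKCSWYPQ
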