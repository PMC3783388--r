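>DIRS_B_RT_m0
QHISGYKMENPTHTINRVFRITYKCMWYPP
>DIRS_B_RT_m1
QHIAGYKMENPTHTINRVFRITYKCMWYPP
>DIRS_B_RT_m2
QHISGYKMENPTHTINRVFRITYKCDWYPP
>DIRS_B_RT_m3
QHISGYKMSNPTHTINRVFRITYKCMWYPP
>DIRS_B_RT_m4
QHISGYKMENPTHTINNVFRITYKCMWYPP
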