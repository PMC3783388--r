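>DIRS_A_RT
THTAEHWGYCQHASLYRMEFPTHTINRVFWITYKCSWYPQTRVPYAAADICFWTIANDSA
>DIRS_B_RT
TSTMEHWGYNQHISGYKMENPTHTINRVFRITYKCMWYPPTRVPYAWAVECWWTIANDSA
>var1_RT
HHTAEHWGYCQHASLYRMEFPTHTINRVFWITYKCSWYPQTRVPLAAADICFWTIANDSA
>var2_RT
TSTMEHWGYNQHISGYKMENSTHTINRVFRITYKCMWYPPTRVPYAWCVECWWTIANDSA
>var3_RT
THTAEHWGYCQHASLYRMEFPTHTINRVFWITYKCSWYPQTRVPYYAADIMFWTIANDSA
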