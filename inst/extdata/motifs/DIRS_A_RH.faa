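>DIRS_A_RH_m0
MFVIQYSFRCKSLSVTPHYIHAMTGGQLYW
>DIRS_A_RH_m1
MKVIQYSFRCKSLSVTPHYIHAMTGGQLYW
>DIRS_A_RH_m2
MFVIQYSFRCRSLSVTPHYIHAMTGGQLYW
>DIRS_A_RH_m3
MFVIQYSFRCKSLSVTPHYIIAMTGGQLYW
>DIRS_A_RH_m4
MFVIQYSFRCKLLSVTPHYIHAMTGGQLYW
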