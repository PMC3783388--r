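>DIRS_B_RH_m0
MFKIQHSFRCKQSQGTTHYIHAMAGEQLYW
>DIRS_B_RH_m1
MFKIQHSFRCKQSQGTTHYIHAMAGETLYW
>DIRS_B_RH_m2
MFKIQHSFRCKQSQGTTHYIHAMACEQLYW
>DIRS_B_RH_m3
MFKIQHSFRCKQSQETTHYIHAMAGEQLYW
>DIRS_B_RH_m4
MFKIQHSFRCKQSQHTTHYIHAMAGEQLYW
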