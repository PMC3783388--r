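>Ngaro1_RH_m0
AFLIPHSFRPRRSSVRTHYQHAMCQTQRYK
>Ngaro1_RH_m1
AFLIPHSFRPRRSSVRTHYQTAMCQTQRYK
>Ngaro1_RH_m2
AFLIPHSFRPRRMSVRTHYQHAMCQTQRYK
>Ngaro1_RH_m3
AFLIPHSFRPRRSSVRTHYQHPMCQTQRYK
>Ngaro1_RH_m4
AFLIPHSFRPRRSSVRTHYQHAMCQTQRYT
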