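>Ngaro1|RT
GFGMEHWFYVFHISQYGMEGPMHTRRAVFWHTYKCSVYIATRVPRANAGGHSCTIANVNA
>Ngaro2|RT
THPMEHWYYVFHISIYGMEGPMHTRRAVFTHTYKCSVYIASRFPRGWAGGHCWTIANVNA
>Ngaro3|RT
TWPMEHWFYVFHISLYGMEGPMETRREVFQHTYKCHFYIATRVPRAWAGGHPWTIANVNA
>Ngaro4|RT
GFPMEHWFAVFHISQYGMENPMHTRRAVFWHTYKCSVYIATRVPRANAHGHSCTIAYVNA
>DIRS_A|RT
THTAEHWGYCQHASLYRMEFPTHTINRVFWITYKCSWYPQTRVPYAAADICFWTIANDSA
>DIRS_B|RT
TSTMEHWGYNQHISGYKMENPTHTINRVFRITYKCMWYPPTRVPYAWAVECWWTIANDSA
>Ngaro1|RH
RCLRCKVDPDAFLIPHSFRPRRSSVRTHYQHAMCQTQRYKWKTGLIETKM
>Ngaro2|RH
LCLRCKVDPDEFEIPMSFRPWRSSVRTHYFHAMCGTQEYKHKTGLIETKN
>Ngaro3|RH
RCKRCKVLPDSFEIIHSFKPLFCSVRTHYQHAMCGTQEYKHKTGLIETKM
>Ngaro4|RH
RCLRCKVDPCAFLIPHSFRGRRSSVRTHYEHAMCQTQRHKWKTGLIETKM
>DIRS_A|RH
RCLRDKFDPHMFVIQYSFRCKSLSVTPHYIHAMTGGQLYWHKMGLLVTSM
>DIRS_B|RH
RCLRDKYDPHMFKIQHSFRCKQSQGTTHYIHAMAGEQLYWCKMGLLVTMM
>Ngaro1|YR
DMSALQRQPRDNVNAYYRCPWWCRHTPEGAYRFHMFQIYLSTSAHPTPKCLKERQMCFVW
>Ngaro2|YR
KMSALQGQPRDVVNSYQRCPWWCAHTQAVAYRKHIFQGKLSTSAHPTPKCLKERQMKFVW
>Ngaro3|YR
DMSALQGQPRDNVNSYQRCPMWWAHTQEGAYRFHMFKGKLSTSAHPTPICLWEVQMCTVW
>Ngaro4|YR
DMSYLQRQPRDNVNAYYRCPWWCRHTNEGAYRFHMFQIYLSTSAHPTPPCLKEDQFCFVW
>DIRS_A|YR
DTYASQGRPRGWENAHQRPPWWCEFTKMAAGLFHMFYWKLSTSAMVAPQCLTHRQKEMSW
>DIRS_B|YR
DTTASQGSIRGNEHAHQRPPWWFAFTQMAANIFHMFYGKLSTSEMVTPQCLTHRQMEMSW
>DIRS_A|MT
TKCMRKQNKRCCRRYLVPKCSQMCKWSYEEMCDQMVKCECPIGLL
>DIRS_B|MT
TKCMRKQWKRCCRRYLPPKCSQIPKWSEEEMCDQQYSCECPIILL
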