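>Ngaro1_RT
GFGMEHWFYVFHISQYGMEGPMHTRRAVFWHTYKCSVYIATRVPRANAGGHSCTIANVNA
>Ngaro2_RT
THPMEHWYYVFHISIYGMEGPMHTRRAVFTHTYKCSVYIASRFPRGWAGGHCWTIANVNA
>Ngaro3_RT
TWPMEHWFYVFHISLYGMEGPMETRREVFQHTYKCHFYIATRVPRAWAGGHPWTIANVNA
>Ngaro4_RT
GFPMEHWFAVFHISQYGMENPMHTRRAVFWHTYKCSVYIATRVPRANAHGHSCTIAYVNA
>var1_RT
GFGYEHWFYVFHISQYGMEGPMHTRRAVFWHWYKCSVYIATRVPRANAGGHSCTIANVNA
>var2_RT
THPMEHWYKVFHISIYGMEGPMHTRRAVFTHTYKCSVYIASRFPRGWAGGCCWTIANVNA
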