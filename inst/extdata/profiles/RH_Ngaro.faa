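>Ngaro1_RH
RCLRCKVDPDAFLIPHSFRPRRSSVRTHYQHAMCQTQRYKWKTGLIETKM
>Ngaro2_RH
LCLRCKVDPDEFEIPMSFRPWRSSVRTHYFHAMCGTQEYKHKTGLIETKN
>Ngaro3_RH
RCKRCKVLPDSFEIIHSFKPLFCSVRTHYQHAMCGTQEYKHKTGLIETKM
>Ngaro4_RH
RCLRCKVDPCAFLIPHSFRGRRSSVRTHYEHAMCQTQRHKWKTGLIETKM
>var1_RH
RCLRCKVDPDAFFIPHSFRPRRSSVRTHYQHAMCQDQRYKWKTGLIETKM
>var2_RH
LCLRCKVDPAEFEIPMSFRPWRSSVRTHYFHAMCGTQEYKHKTELIETKN
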