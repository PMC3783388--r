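>DIRS_A_RH
RCLRDKFDPHMFVIQYSFRCKSLSVTPHYIHAMTGGQLYWHKMGLLVTSM
>DIRS_B_RH
RCLRDKYDPHMFKIQHSFRCKQSQGTTHYIHAMAGEQLYWCKMGLLVTMM
>var1_RH
RCLRDKFDPHMFVIKYSFRCKSLSVDPHYIHAMTGGQLYWHKMGLLVTSM
>var2_RH
RCLRDKYIPHMFKIQHSFRCKQSQGTTHYIHAMAGEQLYQCKMGLLVTMM
>var3_RH
RCLRDKFDPHMFVIQYSFRCKSLSVTPHYIAAKTGGQLYWHKMGLLVTSM
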