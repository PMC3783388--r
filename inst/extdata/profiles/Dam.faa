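>DIRS_A_MT
TKCMRKQNKRCCRRYLVPKCSQMCKWSYEEMCDQMVKCECPIGLL
>DIRS_B_MT
TKCMRKQWKRCCRRYLPPKCSQIPKWSEEEMCDQQYSCECPIILL
>var1_MT
TKCMRKQNKRCCRRYLVPKCSQMCKWSYEEMCDGMVKCFCPIGLL
>var2_MT
TKCMRKQWKRCCRRYLSPKCSQIPKWSEEHMCDQQYSCECPIILL
>var3_MT
TKCMRKQNKRCCRRYLVPKCSIGCKWSYEEMCDQMVKCECPIGLL
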