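id,cdr1,cdr2,cdr3,cdr1_pct_modified,cdr2_pct_modified,cdr3_pct_modified
1,GRTFSNYAIS,RGGDNTAA,VFTPTDTVVFINKEPYNY,18.7,<1,ND
10,GGTFGSYAIS,RSGGSTAA,AGGMGSTTVVVSTIPYKY,NA,NA,ND
22,GRTFSSYAIS,SSGGNTAA,NPATSTVLIVRDLGYAY,NA,<1,<1
30,GRTFSNYAIS,GGGGNTAT,SLTYDQTTVYVSPLAYGD,<1,<1,NA
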