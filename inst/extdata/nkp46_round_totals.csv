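round,total_reads
0,887881
1,1138880
2,754669
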