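cluster_id,reads_r0,reads_r1,reads_r2,reported_ef
1,0,942,2630,3095
2,1,2790,2991,1760
3,36,4964,4147,132
4,888,8573,11954,16
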