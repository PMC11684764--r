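chrom	start_bp	end_bp
1	47761741	51822307
2	129125957	139525961
2	182309767	189427029
3	47483506	49987563
3	83368159	86868160
3	161899518	163699518
5	98636396	101136397
5	129636408	132636409
5	136136412	139136412
6	23691793	38924246
6	139637170	142137170
8	6455071	13598120
8	110918595	113918595
11	88127184	91127184
12	110577812	113099475
14	47061047	47961047
17	42394456	46567318
20	33948533	36438183
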