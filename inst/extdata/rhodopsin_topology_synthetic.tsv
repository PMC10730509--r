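# Implementer-provided default topology for the synthetic rhodopsin-like backbone (1-based inclusive).
segment	start	end
NTERM	1	36
TM1	37	61
ICL1	62	71
TM2	72	100
ECL1	101	105
TM3	106	139
ICL2	140	149
TM4	150	172
ECL2	173	199
TM5	200	225
ICL3	226	252
TM6	253	276
ECL3	277	284
TM7	285	308
H8	309	320
CTERM	321	347
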