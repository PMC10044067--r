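# SYNTHETIC MIC frequency table in EUCAST export layout (two columns:
# MIC mg/L, isolate count). Shaped like a Pseudomonas aeruginosa
# piperacillin wild-type distribution for testing purposes only — NOT the
# real 2023 EUCAST aggregated data, which the user must supply for any
# comparison with published CFR values.
0.5	21
1	180
2	1504
4	3934
8	2420
16	1214
32	534
64	310
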