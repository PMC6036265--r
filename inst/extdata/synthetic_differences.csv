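difference
-0.591
1.634
-1.005
0.320
1.961
-0.353
-0.222
-0.385
-0.036
0.388
1.478
-0.552
-0.830
0.092
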