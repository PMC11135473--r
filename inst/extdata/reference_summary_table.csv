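predictor,re_noec_vs_ec,re_ec_vs_fe,re_noec_vs_fe
E+G,2.573,8.419,2.131
E+G+BRR,1.614,6.574,2.641
E+G+GE,2.489,4.473,3.141
E+G+GE+BRR,4.882,12.138,7.692
Average,2.889,7.901,3.901
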