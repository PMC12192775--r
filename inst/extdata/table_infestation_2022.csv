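orchard,set_a,set_b,set_c,set_d,all_sets,whole_orchard
10,0,0,0,0,0,0.0010
44,0,0,0,0,0,0.0030
15,0,0,0,0,0,0.0018
34,0,0,0,0,0,0.0009
5,0,0,0,0.017,0.004,0.0035
81,0,0,0,0,0,0.0003
19,0,0,0,0,0,0.0001
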