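orchard,set_a,set_b,set_c,set_d,all_sets,whole_orchard
15A,0.20,0.42,0.11,0.33,0.26,0.15
18A,0.00,0.05,0.02,0.00,0.02,0.02
20A,0.27,0.22,0.13,0.16,0.21,0.17
21A,0.04,0.00,0.11,0.29,0.11,0.06
21B,0.25,0.02,0.16,0.11,0.15,0.09
22B,0.40,0.38,0.22,0.58,0.45,0.18
23A,0.29,0.65,0.64,0.22,0.48,0.21
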