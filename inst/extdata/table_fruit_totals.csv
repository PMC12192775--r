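year,orchard,set_a,set_b,set_c,set_d,data_trees,whole_orchard,fruit_per_data_tree_week,fruit_per_orchard_tree_week
2021,15A,42,83,47,52,224,10222,1.24,1.53
2021,18A,23,89,27,16,105,5113,0.58,0.70
2021,20A,61,38,60,36,197,6302,1.09,0.59
2021,21A,14,5,25,58,102,3948,0.57,0.54
2021,21B,35,10,50,36,135,4713,0.75,0.65
2021,22B,61,57,58,96,283,7461,1.57,1.03
2021,23A,67,82,83,37,273,10735,1.51,1.43
2021,Total,NA,NA,NA,NA,1530,53983,1.21,1.09
2022,5,96,38,41,32,223,10670,0.93,0.62
2022,10,39,148,227,101,515,17573,2.14,1.26
2022,15,99,20,29,102,266,20066,1.48,1.20
2022,19,4,6,6,7,28,2128,0.12,0.26
2022,34,203,78,25,56,399,8713,1.67,0.51
2022,44,131,117,112,101,515,17573,2.14,1.26
2022,81,11,44,27,0,89,8609,0.37,0.63
2022,Total,NA,NA,NA,NA,1989,80969,1.18,0.79
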