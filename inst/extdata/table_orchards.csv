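year,orchard,variety,year_planted,area_ha,n_trees
2021,15A,Lane late,2003,1.33,741
2021,18A,Cambria,2003,1.46,810
2021,20A,Cambria,2003,1.30,720
2021,21A,Powell,2003,1.46,813
2021,21B,Powell,2003,1.47,803
2021,22B,Powell,2003,1.46,809
2021,23A,Autumn Gold,2003,1.48,823
2022,5,Autumn Gold,2010,2.58,1435
2022,10,Autumn Gold,2010,2.09,1160
2022,15,Autumn Gold,2010,2.51,1393
2022,19,Midnight,1996,2.58,678
2022,34,Autumn Gold,2010,2.28,1432
2022,44,Witkrans,2009,1.02,1296
2022,81,Midnight,2003,2.05,1137
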