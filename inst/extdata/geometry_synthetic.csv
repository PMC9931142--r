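cell_id,cell_type,S1,S2
a6.5_01,a6.5,0.4548,0.4156
a6.5_02,a6.5,0.3774,0.5178
a6.5_03,a6.5,0.4145,0.4208
a6.5_04,a6.5,0.4253,0.4252
a6.5_05,a6.5,0.4162,0.4377
a6.5_06,a6.5,0.3958,0.4723
a6.5_07,a6.5,0.4605,0.3854
a6.5_08,a6.5,0.3962,0.4224
a6.5_09,a6.5,0.4807,0.3302
a6.5_10,a6.5,0.3975,0.4806
a6.7_01,a6.7,0.2103,0.6792
a6.7_02,a6.7,0.1513,0.7495
a6.7_03,a6.7,0.2157,0.6818
a6.7_04,a6.7,0.2712,0.5944
a6.7_05,a6.7,0.2984,0.5804
a6.7_06,a6.7,0.2054,0.6522
a6.7_07,a6.7,0.2123,0.6583
a6.7_08,a6.7,0.1521,0.7254
a6.7_09,a6.7,0.241,0.6015
a6.7_10,a6.7,0.197,0.6879
a6.6_01,a6.6,0.0916,0.8113
a6.6_02,a6.6,0.069,0.8203
a6.6_03,a6.6,0.1137,0.8051
a6.6_04,a6.6,0.0543,0.8582
a6.6_05,a6.6,0.0287,0.879
a6.6_06,a6.6,0.1007,0.8003
a6.6_07,a6.6,0.0509,0.8626
a6.6_08,a6.6,0.1412,0.7518
a6.6_09,a6.6,0.0661,0.7904
a6.6_10,a6.6,0.1096,0.7904
a6.8_01,a6.8,0.0177,0.8743
a6.8_02,a6.8,0.0398,0.8637
a6.8_03,a6.8,0.0557,0.8564
a6.8_04,a6.8,0.0884,0.7958
a6.8_05,a6.8,0.0033,0.8981
a6.8_06,a6.8,0.0845,0.8232
a6.8_07,a6.8,0.0458,0.8697
a6.8_08,a6.8,0.0739,0.8334
a6.8_09,a6.8,0.0692,0.8185
a6.8_10,a6.8,0.0612,0.8243
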