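stage,name,stripe_freq,blob_count,hue_mix
1,Crown Root Initiation,1,0,0.00
2,Tillering,2,0,0.05
3,Mid Vegetative,4,2,0.20
4,Booting,6,6,0.40
5,Heading,8,12,0.65
6,Anthesis,9,16,0.80
7,Milking,10,20,1.00
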