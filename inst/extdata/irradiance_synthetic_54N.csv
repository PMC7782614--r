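"month","irradiance"
1,25
2,55
3,105
4,165
5,220
6,235
7,225
8,190
9,130
10,70
11,30
12,18
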