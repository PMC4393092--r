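voltage_mV,current_pA
-20,-81.833
-18,-75.197
-16,-67.476
-14,-57.617
-12,-50.064
-10,-41.45
-8,-32.751
-6,-24.189
-4,-15.051
-2,-6.284
0,-1.219
2,7.87
4,13.548
6,24.856
8,34.637
10,39.83
12,51.815
14,59.987
16,67.283
18,74.198
20,81.349
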