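voltage_mV,current_pA
-20,-74.455
-18,-61.199
-16,-59.265
-14,-50.1
-12,-44.269
-10,-33.417
-8,-29.645
-6,-21.039
-4,-13.889
-2,-4.316
0,1.625
2,6.299
4,16.631
6,19.546
8,26.689
10,36.438
12,43.432
14,48.018
16,55.915
18,65.642
20,70.441
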