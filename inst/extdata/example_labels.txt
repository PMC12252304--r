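0 0.250000 0.250000 0.480000 0.470000
0 0.750000 0.250000 0.460000 0.480000
0 0.250000 0.750000 0.470000 0.460000
0 0.750000 0.750000 0.480000 0.480000
1 0.210000 0.300000 0.060000 0.045000
1 0.320000 0.180000 0.052000 0.060000
1 0.700000 0.280000 0.058000 0.050000
1 0.260000 0.720000 0.055000 0.048000
1 0.790000 0.810000 0.050000 0.056000
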