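patient,age_yr,sex,nyha_class,esv_ml,edv_ml,ef_pct
1,83,M,2,228,303,25
2,67,M,3,272,344,21
3,50,M,3,237,324,27
4,85,M,3,216,235,8
5,38,M,2,231,311,26
6,79,M,2,186,217,14
7,41,M,3,220,285,23
8,76,M,2,219,283,23
9,76,M,3,184,276,33
10,72,M,3,200,252,21
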