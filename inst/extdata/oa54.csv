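"c1","c2","c3","c4","c5","c6","c7","c8","c9","c10","c11","c12","c13","c14","c15","c16","c17","c18","c19","c20","c21","c22","c23","c24","c25","c26"
1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1
1,1,1,1,1,2,2,2,2,2,2,3,3,3,1,1,1,2,2,2,2,2,2,3,3,3
1,1,1,1,1,3,3,3,3,3,3,2,2,2,1,1,1,3,3,3,3,3,3,2,2,2
1,1,2,2,2,1,1,1,2,2,2,2,2,2,2,2,2,1,1,1,2,2,2,2,2,2
1,1,2,2,2,2,2,2,3,3,3,1,1,1,2,2,2,2,2,2,3,3,3,1,1,1
1,1,2,2,2,3,3,3,1,1,1,3,3,3,2,2,2,3,3,3,1,1,1,3,3,3
1,1,3,3,3,1,1,1,3,3,3,3,3,3,3,3,3,1,1,1,3,3,3,3,3,3
1,1,3,3,3,2,2,2,1,1,1,2,2,2,3,3,3,2,2,2,1,1,1,2,2,2
1,1,3,3,3,3,3,3,2,2,2,1,1,1,3,3,3,3,3,3,2,2,2,1,1,1
1,2,1,2,3,1,2,3,1,2,3,1,2,3,2,3,1,2,3,1,2,3,1,2,3,1
1,2,1,2,3,2,3,1,2,3,1,3,1,2,2,3,1,3,1,2,3,1,2,1,2,3
1,2,1,2,3,3,1,2,3,1,2,2,3,1,2,3,1,1,2,3,1,2,3,3,1,2
1,2,2,3,1,1,2,3,2,3,1,2,3,1,3,1,2,2,3,1,3,1,2,3,1,2
1,2,2,3,1,2,3,1,3,1,2,1,2,3,3,1,2,3,1,2,1,2,3,2,3,1
1,2,2,3,1,3,1,2,1,2,3,3,1,2,3,1,2,1,2,3,2,3,1,1,2,3
1,2,3,1,2,1,2,3,3,1,2,3,1,2,1,2,3,2,3,1,1,2,3,1,2,3
1,2,3,1,2,2,3,1,1,2,3,2,3,1,1,2,3,3,1,2,2,3,1,3,1,2
1,2,3,1,2,3,1,2,2,3,1,1,2,3,1,2,3,1,2,3,3,1,2,2,3,1
1,3,1,3,2,1,3,2,1,3,2,1,3,2,2,1,3,2,1,3,2,1,3,2,1,3
1,3,1,3,2,2,1,3,2,1,3,3,2,1,2,1,3,3,2,1,3,2,1,1,3,2
1,3,1,3,2,3,2,1,3,2,1,2,1,3,2,1,3,1,3,2,1,3,2,3,2,1
1,3,2,1,3,1,3,2,2,1,3,2,1,3,3,2,1,2,1,3,3,2,1,3,2,1
1,3,2,1,3,2,1,3,3,2,1,1,3,2,3,2,1,3,2,1,1,3,2,2,1,3
1,3,2,1,3,3,2,1,1,3,2,3,2,1,3,2,1,1,3,2,2,1,3,1,3,2
1,3,3,2,1,1,3,2,3,2,1,3,2,1,1,3,2,2,1,3,1,3,2,1,3,2
1,3,3,2,1,2,1,3,1,3,2,2,1,3,1,3,2,3,2,1,2,1,3,3,2,1
1,3,3,2,1,3,2,1,2,1,3,1,3,2,1,3,2,1,3,2,3,2,1,2,1,3
2,1,1,1,2,1,1,2,1,1,2,1,1,2,3,3,2,3,3,2,3,3,2,3,3,2
2,1,1,1,2,2,2,3,2,2,3,3,3,1,3,3,2,1,1,3,1,1,3,2,2,1
2,1,1,1,2,3,3,1,3,3,1,2,2,3,3,3,2,2,2,1,2,2,1,1,1,3
2,1,2,2,3,1,1,2,2,2,3,2,2,3,1,1,3,3,3,2,1,1,3,1,1,3
2,1,2,2,3,2,2,3,3,3,1,1,1,2,1,1,3,1,1,3,2,2,1,3,3,2
2,1,2,2,3,3,3,1,1,1,2,3,3,1,1,1,3,2,2,1,3,3,2,2,2,1
2,1,3,3,1,1,1,2,3,3,1,3,3,1,2,2,1,3,3,2,2,2,1,2,2,1
2,1,3,3,1,2,2,3,1,1,2,2,2,3,2,2,1,1,1,3,3,3,2,1,1,3
2,1,3,3,1,3,3,1,2,2,3,1,1,2,2,2,1,2,2,1,1,1,3,3,3,2
2,2,1,2,1,1,2,1,1,2,1,1,2,1,3,2,3,3,2,3,3,2,3,3,2,3
2,2,1,2,1,2,3,2,2,3,2,3,1,3,3,2,3,1,3,1,1,3,1,2,1,2
2,2,1,2,1,3,1,3,3,1,3,2,3,2,3,2,3,2,1,2,2,1,2,1,3,1
2,2,2,3,2,1,2,1,2,3,2,2,3,2,1,3,1,3,2,3,1,3,1,1,3,1
2,2,2,3,2,2,3,2,3,1,3,1,2,1,1,3,1,1,3,1,2,1,2,3,2,3
2,2,2,3,2,3,1,3,1,2,1,3,1,3,1,3,1,2,1,2,3,2,3,2,1,2
2,2,3,1,3,1,2,1,3,1,3,3,1,3,2,1,2,3,2,3,2,1,2,2,1,2
2,2,3,1,3,2,3,2,1,2,1,2,3,2,2,1,2,1,3,1,3,2,3,1,3,1
2,2,3,1,3,3,1,3,2,3,2,1,2,1,2,1,2,2,1,2,1,3,1,3,2,3
2,3,1,3,3,1,3,3,1,3,3,1,3,3,1,2,2,1,2,2,1,2,2,1,2,2
2,3,1,3,3,2,1,1,2,1,1,3,2,2,1,2,2,2,3,3,2,3,3,3,1,1
2,3,1,3,3,3,2,2,3,2,2,2,1,1,1,2,2,3,1,1,3,1,1,2,3,3
2,3,2,1,1,1,3,3,2,1,1,2,1,1,2,3,3,1,2,2,2,3,3,2,3,3
2,3,2,1,1,2,1,1,3,2,2,1,3,3,2,3,3,2,3,3,3,1,1,1,2,2
2,3,2,1,1,3,2,2,1,3,3,3,2,2,2,3,3,3,1,1,1,2,2,3,1,1
2,3,3,2,2,1,3,3,3,2,2,3,2,2,3,1,1,1,2,2,3,1,1,3,1,1
2,3,3,2,2,2,1,1,1,3,3,2,1,1,3,1,1,2,3,3,1,2,2,2,3,3
2,3,3,2,2,3,2,2,2,1,1,1,3,3,3,1,1,3,1,1,2,3,3,1,2,2
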