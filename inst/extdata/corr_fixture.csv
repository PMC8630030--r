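x,y
0.5,2.1
1.2,1.8
2.3,3.9
3.1,3.2
4.8,6.1
5.5,5.0
6.1,7.4
7.9,7.0
8.4,9.2
9.9,8.8
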