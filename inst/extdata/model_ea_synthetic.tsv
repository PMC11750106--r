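g	N
0	1000000
50	400000
100	150000
200	60000
500	30000
1000	20000
2000	5000
3000	14000
5000	24000
10000	28000
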