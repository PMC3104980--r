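7
4
5
3
1
5
7
6
4
3
2
6
6
9
2
3
3
7
2
5
5
4
4
8
8
7
2
6
3
5
0
5
8
9
3
4
5
4
6
1
0
5
4
6
3
6
9
5
7
6
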