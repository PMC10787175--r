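3	3	3	0
2	2	2	0
1	1	0	0
5	5	5	5
2	2	2	2
3	3	3	3
2	2	0	0
4	4	4	4
1	1	1	0
2	0	2	2
3	3	3	3
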