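A	C	G	T
2	1	35	2
34	2	2	2
1	1	2	36
35	2	1	2
28	4	4	4
4	4	28	4
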