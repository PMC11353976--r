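code	weight
F00	7.1
E11	2.1
I10	1.6
E78	0.9
N18	4.2
D64	1.9
G47	1.1
M54	0.5
J45	0.8
F32	1.4
K21	0.3
B20	2.7
C50	3.3
E66	1.2
R51	0.4
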