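LFS01	1	0	0	1	0	0	0	62	-9
LFS01	2	0	0	2	0	0	1	54	54	OT	45	1
LFS01	3	1	2	2	1	1	0	33	-9	BR	28	1
LFS01	4	1	2	1	0	0	0	36	-9	SA	12	1
LFS01	5	0	0	1	0	0	0	35	-9
LFS01	6	5	3	2	0	0	0	8	-9
LFS01	7	5	3	1	0	0	0	5	-9
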