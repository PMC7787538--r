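publication	c1	c2	c3	c4	c5	c6	c7	c8	c9	c10
p1	3	0	0	0	7	0	3	6	3	0
p2	0	3	7	3	0	0	0	3	0	4
p3	3	3	5	0	0	6	0	0	4	0
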