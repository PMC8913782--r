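gene	c1	c2	c3	c4	c5	c6	c7	c8	c9
CD79A	10	9	10	0	0	0	0	0	0
CD79B	9	10	8	0	0	0	0	0	0
CD19	10	10	9	0	0	0	0	0	0
MS4A1	8	9	10	0	0	0	0	0	0
SDC1	0	0	0	10	9	10	0	0	0
PRDM1	0	0	0	9	10	8	0	0	0
CD3D	0	0	0	0	0	0	10	9	10
CD3E	0	0	0	0	0	0	9	10	8
ACTB	5	5	5	5	5	5	5	5	5
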