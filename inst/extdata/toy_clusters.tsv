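cell_id	cluster
c1	1
c2	1
c3	1
c4	2
c5	2
c6	2
c7	3
c8	3
c9	3
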