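gene	S1	S2	S3
G1	10	0	25.5
G2	3	7	0
G3	120	64	1
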