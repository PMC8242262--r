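chr1	0	500000	A
chr1	500000	1000000	B
chr1	1000000	1500000	A
chr1	1500000	2000000	B
chr2	0	500000	B
chr2	500000	1000000	A
chr2	1000000	1500000	B
chr2	1500000	2000000	A
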