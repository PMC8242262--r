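chr1	125398	225398	LAD
chr1	548503	948503	LAD
chr1	1217213	1317213	LAD
chr1	1591076	1991076	LAD
chr2	5767	405767	LAD
chr2	771640	871640	LAD
chr2	1070539	1470539	LAD
chr2	1702681	1802681	LAD
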