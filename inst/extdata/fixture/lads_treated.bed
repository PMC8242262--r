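chr1	125398	148683	LAD
chr1	564486	948503	LAD
chr1	1614542	1991076	LAD
chr2	5767	201235	LAD
chr2	251235	405767	LAD
chr2	1075598	1470539	LAD
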