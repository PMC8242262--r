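chr1	148683	448683	GSR
chr1	514486	564486	GSR
chr1	1056574	1356574	GSR
chr1	1564542	1614542	GSR
chr2	201235	251235	GSR
chr2	601520	901520	GSR
chr2	1025598	1075598	GSR
chr2	1615332	1915332	GSR
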