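sample	reads_exogenous	reads_endogenous
input	1e+06	4e+06
control	1e+06	4e+06
treated	1e+06	4e+06
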