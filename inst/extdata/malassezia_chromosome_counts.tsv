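species	chromosomes
Msl	9
Mf	7
Mjap	9
Mves	9
Mg	9
Mr	9
Msy	8
Md	8
Mn	8
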