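303	315
515	525
16182	16194
16519	16519
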