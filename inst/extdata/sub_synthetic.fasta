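>SUB synthetic: printed interface peptide 130-161 with glycine filler flanks
GGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGG
GGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGG
GGGGGGGGGSTKLAEQYDTFVKFTYDQIQKRFEGATPSYLSGGGGGGGGGG
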