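domain	aa_start	aa_end
methyltransferase	8	85
DNA_binding	92	176
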