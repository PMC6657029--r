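structure_id	position
synt1	231
synt1	207
synt2	231
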