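TGT01
TGT02
TGT03
TGT04
TGT05
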