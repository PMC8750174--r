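INT01
INT02
INT03
INT04
INT05
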