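drug_code	name	status	gene
D09GYT	Methoxamine	approved	TGT05
D0T6SU	Phendimetrazine	approved	TGT01
D0AZ3C	Imatinib	approved	INT02
D03LJR	SIROLIMUS	approved	INT03
D0K3QS	Everolimus	approved	INT04
D0ES1Q	Temsirolimus	approved	INT05
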