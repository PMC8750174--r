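drug_id	name	group	gene
DB00114	Pyridoxal phosphate	approved	TGT01
DB00114	Pyridoxal phosphate	approved	INT01
DB00321	Amitriptyline	approved	TGT02
DB00321	Amitriptyline	approved	INT02
DB00668	Epinephrine	approved	TGT03
DB00668	Epinephrine	approved	INT03
DB01427	Amrinone	approved	TGT04
DB01427	Amrinone	approved	INT04
DB06637	Dalfampridine	approved	TGT05
DB06637	Dalfampridine	approved	INT05
DB15035	Zanubrutinib	approved	TGT01
DB15035	Zanubrutinib	approved	INT02
DB01133	Tiludronic acid	approved	TGT02
DB01133	Tiludronic acid	approved	INT03
DB01593	Zinc	approved	TGT03
DB01593	Zinc	approved	INT04
DB14487	Zinc acetate	approved	TGT04
DB14487	Zinc acetate	approved	INT05
DB14533	Zinc chloride	approved	TGT05
DB14533	Zinc chloride	approved	INT01
DB14548	Zinc sulfate	approved	TGT01
DB14548	Zinc sulfate	approved	INT03
DB12010	Fostamatinib	approved	TGT02
DB12010	Fostamatinib	approved	INT04
DB04272	Citric acid	approved	TGT03
DB04272	Citric acid	approved	INT05
DB09130	Copper	approved	TGT04
DB09130	Copper	approved	INT01
DB00723	Methoxamine	approved	TGT05
DB01579	Phendimetrazine	approved	TGT01
DB00619	Imatinib	approved	INT02
DB00877	Sirolimus	approved	INT03
DB01590	Everolimus	approved	INT04
DB06287	Temsirolimus	approved	INT05
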