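accession	name	motifs
At1g64770	AtNDF2	IDALQIELSCTAGV;IVSLYPVSMATALV
At1g80030	AtDjA7	ISYLDAILGAVVKV
At2g21530	FHA-domain-protein	IGRLPEKADVVIPV
At2g35490	PAP	IPLLAAGSTPLLKV
At2g36145	Unknown	IDCLVFQTTENGVV
At2g43560	AtFKBP16-3	ISNLSSRREAMLLV
At3g04790	Ribose-5P-isomerase	IGKLLSSGELYDIV
At3g46780	AtPTAC16	IASLVADIFANTAV
At4g39710	AtFKBP16-2	IRGLDQGILGGEGV
At5g39830	AtDeg8	ISGLNRDIFSQTGV
At5g52970	TL15	IANLEKDTGFKLRV
At5g67030	AtLOS6	INGLVDGISGTWYV
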