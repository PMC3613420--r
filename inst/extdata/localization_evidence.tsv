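accession	name	group	chl_score	mt_score	sec_score	tools	chloroplast2010	msms
At3g52190	AtPHF1	gef	7.6	0	0.3	MultiLoc;PCLR;SLPFA;TargetP	Chl.	.
At1g72150	AtPATL1	receptor	2.3	0	0	.	Chl.	yes
At4g09160	SEC14-like	receptor	4.7	0	0	TargetP	Chl.	yes
At1g22530	SEC14-like	receptor	3.1	0	0	.	Chl.	yes
At5g63060	SEC14-like	sec14	18.1	4.2	0.4	.	Chl.	yes
At2g16380	AtSFH7	sec14	5.2	0	0	ChloroP;PCLR;PredSL	.	.
At3g46450	SEC14-like	sec14	6.7	4.2	0	ChloroP;PCLR;PProwler;WoLFPSORT	.	.
At2g18180	AtSFH10	sec14	5	0	0	BacelLo;MultiLoc;PredSL;Plant-mPloc;TargetP	.	.
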