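# Synthetic catalytic-site annotation table (NOT from the Catalytic Site Atlas).
# Hand-written stand-in encoding textbook catalytic chemistries, used only to
# give the package a working default co-occurrence profile; rebuild from a real
# CSA dump for production use.
# columns: structure_id  chain  resnum  icode  site_id  aa
SYN001	A	57		1	HIS
SYN001	A	102		1	ASP
SYN001	A	195		1	SER
SYN002	A	64		1	HIS
SYN002	A	32		1	ASP
SYN002	A	221		1	SER
SYN003	A	285		1	SER
SYN003	A	263		1	HIS
SYN003	A	82		1	GLU
SYN004	A	25		1	CYS
SYN004	A	163		1	HIS
SYN004	A	187		1	ASN
SYN005	A	145		1	CYS
SYN005	A	41		1	HIS
SYN005	A	161		1	ASN
SYN006	A	199		1	ASP
SYN006	A	255		1	GLU
SYN006	A	329		1	ASP
SYN007	A	52		1	GLU
SYN007	A	35		1	GLU
SYN008	A	32		1	ASP
SYN008	A	215		1	ASP
SYN009	A	142		1	HIS
SYN009	A	146		1	HIS
SYN009	A	166		1	GLU
SYN010	A	94		1	HIS
SYN010	A	96		1	HIS
SYN010	A	119		1	HIS
SYN011	A	229		1	LYS
SYN011	A	361		1	TYR
SYN012	A	345		1	LYS
SYN012	A	396		1	LYS
SYN012	A	159		1	HIS
SYN013	A	12		1	CYS
SYN013	A	18		1	ARG
SYN013	A	129		1	ASP
SYN014	A	12		1	HIS
SYN014	A	119		1	HIS
SYN014	A	41		1	LYS
SYN015	A	215		1	SER
SYN015	A	440		1	HIS
SYN015	A	327		1	GLU
SYN016	A	70		1	GLU
SYN016	A	35		1	ASP
SYN016	A	108		1	TYR
SYN017	A	1		1	THR
SYN017	A	17		1	LYS
SYN017	A	33		1	ASP
SYN018	A	78		1	ARG
SYN018	A	52		1	ASP
SYN018	A	110		1	GLN
SYN019	A	155		1	TRP
SYN019	A	144		1	GLU
SYN019	A	172		1	ASP
SYN020	A	49		1	THR
SYN020	A	171		1	HIS
SYN020	A	246		1	GLU
SYN021	A	88		1	TYR
SYN021	A	115		1	LYS
SYN021	A	140		1	SER
SYN022	A	73		1	ARG
SYN022	A	100		1	GLU
SYN022	A	131		1	HIS
SYN023	A	233		1	GLY
SYN023	A	234		1	SER
SYN023	A	105		1	HIS
SYN024	A	60		1	GLY
SYN024	A	63		1	ASP
SYN024	A	94		1	LYS
SYN025	A	202		1	ASN
SYN025	A	257		1	GLU
SYN025	A	301		1	ASP
SYN026	A	6		1	GLN
SYN026	A	48		1	HIS
SYN026	A	120		1	ARG
SYN027	A	300		1	SER
SYN027	A	187		1	ASP
SYN027	A	224		1	HIS
SYN028	A	55		1	GLU
SYN028	A	113		1	HIS
SYN028	A	143		1	TYR
SYN029	A	97		1	CYS
SYN029	A	42		1	ASP
SYN030	A	152		1	LYS
SYN030	A	210		1	ASP
SYN030	A	253		1	GLU
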