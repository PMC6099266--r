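id	case	site	stratum	sex	age_band	smoking	alcohol	pc1	pc2
S01	TRUE	oral	Europe	male	50-60	current	ever	0.12	-0.44
S02	FALSE	control	Europe	female	60-70	never	never	-0.31	0.25
S03	TRUE	oropharyngeal	Europe	male	<=50	previous	ever	0.56	0.02
S04	FALSE	control	North America	female	>=70	never	ever	-1.02	0.77
S05	TRUE	oral	North America	male	60-70		ever	0.44	-0.13
S06	FALSE	control	Europe	male	50-60	current	ever	0.09	0.31
S07	TRUE	oropharyngeal	North America	female	50-60	previous	never	-0.25	-0.66
S08	FALSE	control	North America	male	60-70	never	ever	0.71	0.12
S09	TRUE	oral	Europe	female	<=50	current		-0.48	0.55
S10	FALSE	control	Europe	male	>=70	previous	ever	0.33	-0.21
S11	TRUE	oral	Europe	male	50-60	never	ever	0.00	0.00
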