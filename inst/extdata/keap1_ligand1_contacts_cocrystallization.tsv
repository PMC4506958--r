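residue	protein_atom	water	ligand_atom	type	distance
Tyr334	CG		CAL	NP	3.34
Tyr334	OH		NAO	HB	3.07
Arg336	NE		CAD	NP	3.25
Arg336	NE		CAI	NP	3.34
Arg336	NE		CAF	NP	3.39
Arg336	O	W413		HB	2.66
		W413	NAP	HB	2.50
Ser363	CB		OAA	NP	3.10
Ser363	OG		OAA	HB	2.57
Ser363	OG		CAT	NP	3.21
Ser363	OG		OAC	NP	3.31
Arg380	NE		OAC	HB	2.88
Arg380	CZ		OAC	NP	3.30
Arg380	NH2		OAC	HB	2.88
Arg380	NH2		OAQ	NP	3.22
Asn382	CB		OAC	NP	3.21
Asn382	ND2		OAC	HB	3.05
Asn382	ND2		OAQ	NP	3.31
Asn414	OD1	W433		HB	2.81
		W433	OAA	HB	3.07
Ser602	OG	W424		HB	2.79
		W424	OAA	HB	2.90
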