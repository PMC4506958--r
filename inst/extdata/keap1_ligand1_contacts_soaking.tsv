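residue	protein_atom	water	ligand_atom	type	distance
Tyr334	CE2		CAZ	NP	3.19
Tyr334	CZ		CAY	NP	3.37
Tyr334	OH		CAY	NP	3.30
Tyr334	OH		CAI	NP	3.14
Tyr334	OH		CAD	NP	3.33
Ser363	OG		NAM	NP	3.39
Ser363	OG		OAB	NP	3.40
Arg380	NH2		NAN	NP	3.07
Asn382	CG		OAR	NP	3.02
Asn382	OD1		OAR	NP	2.91
Asn382	OD1		CAF	NP	3.03
Asn414	OD1	W445		HB	2.67
		W445	OAB	HB	2.58
Arg415	NH1		OAA	ES	3.51
Arg415	NH1		OAQ	NP	3.05
Arg415	NH2		NAP	NP	3.08
Arg415	NH2		CAX	NP	3.20
Arg415	NH2		CAU	NP	3.26
Arg483	NE		OAC	ES	3.47
Arg483	NH2		OAC	ES	3.44
Ser508	CB		OAC	NP	3.14
Ser508	OG		OAC	HB	2.74
Ser508	OG		CAT	NP	3.12
Ala556	CB		CAV	NP	3.39
Gly603	CA		CAK	NP	3.11
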