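macromolecule	fraction_pct	monomer_id	monomer_mw	within_fraction
protein	50.1	protein_monomer[c]	110.0	1.0
dna	3.0	dna_monomer[c]	330.0	1.0
rna	8.5	rna_monomer[c]	340.0	1.0
phospholipid	0.9	phospholipid_unit[c]	750.0	1.0
peptidoglycan	2.5	peptidoglycan_unit[c]	1000.0	1.0
lipopolysaccharide	3.4	lps_unit[c]	2000.0	1.0
polysaccharide	15.7	glucan_unit[c]	162.0	1.0
phb	15.9	phb_monomer[c]	86.0	1.0
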