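species	group	n_sat_families	repeatome_percent	satellite_percent
Meconema thalassinum	tettigoniidae	246	92	16
Pholidoptera griseoaptera	tettigoniidae	10	85	5.65
Ruspolia dubia	tettigoniidae	104	60	17.2
Ruspolia yunnana	tettigoniidae	84	59	10.7
Elimaea pallidus	tettigoniidae	45	52	NA
Atlanticus sinensis	tettigoniidae	33	60	11.6
Mecopoda bonneti	tettigoniidae	37	64	11.7
Gampsocleis gratiosa	tettigoniidae	30	62	9.11
Phryganogryllacris superangulata	outgroup	17	34	7
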