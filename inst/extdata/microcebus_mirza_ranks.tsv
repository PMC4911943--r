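2005	Microcebus	genus
2005	Microcebus_berthae	species
2005	Microcebus_griseorufus	species
2005	Microcebus_murinus	species
2005	Microcebus_myoxinus	species
2005	Microcebus_ravelobensis	species
2005	Microcebus_rufus	species
2005	Microcebus_sambiranensis	species
2005	Microcebus_tavaratra	species
2005	Mirza	genus
2005	Mirza_coquereli	species
1993	Microcebus	genus
1993	Microcebus_murinus	species
1993	Microcebus_rufus	species
1993	Microcebus_coquereli	species
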