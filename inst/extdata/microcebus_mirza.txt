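taxonomy 2005 Microcebus/Mirza sec. 2005
(Microcebus Microcebus_berthae Microcebus_griseorufus Microcebus_murinus Microcebus_myoxinus Microcebus_ravelobensis Microcebus_rufus Microcebus_sambiranensis Microcebus_tavaratra)
(Mirza Mirza_coquereli)

taxonomy 1993 Microcebus sec. 1993
(Microcebus Microcebus_murinus Microcebus_rufus Microcebus_coquereli)

articulation fig1 2005-1993
[2005.Microcebus_griseorufus is_included_in 1993.Microcebus_murinus]
[2005.Microcebus_murinus is_included_in 1993.Microcebus_murinus]
[2005.Microcebus_myoxinus is_included_in 1993.Microcebus_murinus]
[2005.Microcebus_berthae disjoint 1993.Microcebus]
[2005.Microcebus_ravelobensis disjoint 1993.Microcebus]
[2005.Microcebus_sambiranensis disjoint 1993.Microcebus]
[2005.Microcebus_tavaratra disjoint 1993.Microcebus]
[2005.Microcebus_rufus equals 1993.Microcebus_rufus]
[2005.Mirza_coquereli equals 1993.Microcebus_coquereli]
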