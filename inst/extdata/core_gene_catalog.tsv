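gene	ac_alias	category	match_aliases
dnapol	ac65	replication	dnapol|DNA polymerase
helicase	ac95	replication	helicase
lef-1	ac14	replication	lef-1|DNA primase
lef-2	ac6	replication	lef-2|late expression factor 2
lef-4	ac90	transcription	lef-4|late expression factor 4
lef-5	ac99	transcription	lef-5|late expression factor 5
lef-8	ac50	transcription	lef-8|late expression factor 8
lef-9	ac62	transcription	lef-9|late expression factor 9
vlf-1	ac77	transcription	vlf-1|very late expression factor 1
p47	ac40	transcription	p47
p74	ac138	virus entry	p74
pif-1	ac119	virus entry	pif-1|per-os infectivity factor 1
pif-2	ac22	virus entry	pif-2|per-os infectivity factor 2
pif-3	ac115	virus entry	pif-3|per-os infectivity factor 3
ld130	ac23	virus entry	ld130|gp64|fusion protein
p91	ac83	structural	p91|vp91
38K	ac98	structural	38K|38kDa
odv-e56	ac148	structural	odv-e56
odv-e27	ac144	structural	odv-e27
gp41	ac80	structural	gp41
p6.9	ac100	structural	p6.9
vp39	ac89	structural	vp39
vp1054	ac54	structural	vp1054
alk-exo	ac133	auxiliary	alk-exo|alkaline exonuclease
ac81	ac81	unknown	ac81
19K	ac96	unknown	19K|19kDa|ac96
ac68	ac68	unknown	ac68
ac92	ac92	unknown	ac92
ac109	ac109	unknown	ac109
ac142	ac142	unknown	ac142
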