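name	notation	alphabet	context
very_late_promoter	DTAAG	dna	baculovirus very-late promoter motif recognized by VLF-1
late_promoter	TAAG	dna	baculovirus late promoter core; absent in the 500 bp upstream of Hz2V062
capping_enzyme_KxDG	KxDG	protein	RNA capping enzyme guanylation motif; Hz2V043 at 641 aa and 764 aa
esterase_GxSxG	GxSxG	protein	serine esterase catalytic motif; partially conserved in Hz2V007 at 191 aa
jhe_RF	RF	protein	juvenile hormone esterase catalytic motif; Hz2V007 at 53 aa
jhe_DQ	DQ	protein	juvenile hormone esterase catalytic motif; partially conserved in Hz2V007 at 165 aa
jhe_E	E	protein	juvenile hormone esterase catalytic residue; not identified in Hz2V007
jhe_GxxHxxDE	GxxHxxD/E	protein	juvenile hormone esterase catalytic motif; Hz2V007 at 544 aa
polb_catalytic	YxDTD	protein	DNA polymerase B catalytic motif; Hz2V018 at 892-897 aa
polb_nucleotide_binding	K(3x)NS(x)YG(2x)G	protein	DNA polymerase B nucleotide-binding motif; Hz2V018 at 842-853 aa
rnapol_lef8	GxKx4HGQ/NKG	protein	RNA polymerase conserved motif; Hz2V051 at 858-869 aa
lef9_HADQDGD	HADQDGD	protein	RNA polymerase large-subunit motif variant; Hz2V063 at 286-292 aa
lef9_NTDCDGD	NTDCDGD	protein	AcMNPV LEF-9 RNA polymerase motif
rnapol_NADFDGD	NADFDGD	protein	vaccinia RNA polymerase large-subunit motif
gmpk_ploop	G-X2-G-X-G-K	protein	GMP kinase catalytic P-loop; Hz2V034 at 61-67 aa with one mismatch
mmp_active_site	HEXXHXUGUXH	protein	zinc metalloprotease active site; Hz2V068 at 412-422 aa (reported span 412-122 is an evident start/end typo)
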