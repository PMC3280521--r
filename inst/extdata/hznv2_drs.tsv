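dr_id	start	end	score	unit_size	count	pct_id	consensus
dr1	11711	12310	134	24	25	63.2	atgaagctgaggatgaatctgaac
dr2	174285	174572	132	36	8	79.2	gaaactcctaaatcaaaggatgaacctaaagcaaag
dr3	175417	175656	124	60	4	88.3	atgaaaaagcaaaggctgaggcgaaggctaaagccgatgctgctgcaaaagccaaagctg
dr4	178103	178390	182	24	12	85.8	ttataccagagagcaagccagaaa
dr5	178517	178921	104	81	5	72.8	acctaaagttgaatctaaagtagtggaaccacctaaagcggaatctaaaacagtggaagctcctactaaaacagttgaagt
dr6	180236	180445	156	30	7	94.3	agctgccgctaaacgcaaagccgaggctga
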