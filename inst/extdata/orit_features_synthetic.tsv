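label	start	end
LysR_motif_1	120	142
LysR_motif_2	200	222
conserved20	281	300
REPT1	301	318
REPT2	350	380
REPT3	400	430
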