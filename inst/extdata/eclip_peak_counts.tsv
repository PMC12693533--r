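rbp	cell_line	n_peaks
TIA1	K562	5885
U2AF2	HepG2	10732
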