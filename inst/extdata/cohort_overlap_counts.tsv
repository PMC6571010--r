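caller	identified	tp	fp	fn
ericscript	17	10	7	19
fusioncatcher	22	22	0	7
jaffa	21	19	2	10
meta-caller	19	19	0	10
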