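gene	lnL0	lnL1
rps5	-6492.11	-6275.91
atpI	-9013.33	-8757.67
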