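driver_core	toggle-switch driver genes	g1	g2
activated_responders	responders with strong activating coupling	r1	r3	r5	r7
inhibited_responders	responders with strong inhibiting coupling	r2	r4	r6	r8
absent_genes	genes not present in the simulated matrix	foo	bar	baz
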