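chr4	55095263	55164414	PDGFRA
chr12	58141509	58149796	CDK4
chr9	21967750	21995300	CDKN2A
chrX	39909067	39956009	BCOR
chr17	29421944	29709134	NF1
chr17	7571719	7590868	TP53
chr7	116312443	116438440	MET
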