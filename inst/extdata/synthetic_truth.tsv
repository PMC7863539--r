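otu_a	otu_b	kind	leak_rate
OTU_0001	OTU_0002	equivalent	0.02
OTU_0003	OTU_0004	high_low	0.02
OTU_0005	OTU_0006	low_low	0.02
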