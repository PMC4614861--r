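comparison	group_a	group_b	mya
non_human_primates_vs_human	XP_003278601.1;ENSGGOP00000008197;ABX89284.1	NP_076985.4	30
mammalian_radiation	NP_001104239.1;ACU30144.1;XP_003133798.1;NP_599198.2	NP_076985.4	96
marsupial_vs_eutherian	ENSSHAP00000003620	NP_076985.4	160
birds_vs_amphibians	ENSTGUP00000003679;ENSGALP00000039026	NP_001155066.1	360
amphibians_vs_mammals	NP_001155066.1	NP_076985.4	390
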