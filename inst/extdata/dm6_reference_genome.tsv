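island_type	count	median_length	long_count
CpG	15180	733	260
CpA	40704	692	1100
CpT	42045	694	777
CpC	0	NA	0
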