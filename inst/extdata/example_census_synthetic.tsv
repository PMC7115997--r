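sample	vesicle_count	micelle_count	protomers_per_oligomer	labeling_efficiency	bare_fraction
low_reconstitution	1200	2400	4	0.9	0.4
high_reconstitution	1000	16000	4	0.9	0.1
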