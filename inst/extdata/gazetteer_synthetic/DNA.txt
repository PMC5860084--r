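cdkn2a
tp53
plasmid
oncogene
promoter
exon
microsatellite
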