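p53
kras
egfr
brca1
akt
vegf
myc
pten
tnf
il-6
caspase-3
bcl-2
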