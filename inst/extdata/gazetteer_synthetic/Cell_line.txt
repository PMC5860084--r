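hela
mcf-7
a549
hct116
hek293
jurkat
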