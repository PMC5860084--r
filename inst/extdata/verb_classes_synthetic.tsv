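lemma	class_id
induce	VC1
trigger	VC1
stimulate	VC1
promote	VC1
activate	VC1
inhibit	VC2
suppress	VC2
block	VC2
repress	VC2
attenuate	VC2
increase	VC3
enhance	VC3
elevate	VC3
upregulate	VC3
decrease	VC4
reduce	VC4
downregulate	VC4
diminish	VC4
express	VC5
overexpress	VC5
encode	VC5
observe	VC6
detect	VC6
measure	VC6
assess	VC6
correlate	VC7
associate	VC7
link	VC7
regulate	VC8
mediate	VC8
modulate	VC8
control	VC8
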