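kind	key1	key2	value
stack	AU	AU	-0.93
stack	AU	UA	-1.1
stack	AU	CG	-2.24
stack	AU	GC	-2.08
stack	AU	GU	-1.2
stack	AU	UG	-1.2
stack	UA	AU	-1.33
stack	UA	UA	-0.93
stack	UA	CG	-2.35
stack	UA	GC	-2.11
stack	UA	GU	-1.2
stack	UA	UG	-1.2
stack	CG	AU	-2.11
stack	CG	UA	-2.08
stack	CG	CG	-3.26
stack	CG	GC	-2.36
stack	CG	GU	-1.2
stack	CG	UG	-1.2
stack	GC	AU	-2.35
stack	GC	UA	-2.24
stack	GC	CG	-3.42
stack	GC	GC	-3.26
stack	GC	GU	-1.2
stack	GC	UG	-1.2
stack	GU	AU	-1.2
stack	GU	UA	-1.2
stack	GU	CG	-1.2
stack	GU	GC	-1.2
stack	GU	GU	-0.5
stack	GU	UG	-0.5
stack	UG	AU	-1.2
stack	UG	UA	-1.2
stack	UG	CG	-1.2
stack	UG	GC	-1.2
stack	UG	GU	-0.5
stack	UG	UG	-0.5
loop_open	NA	NA	3
loop_ext	NA	NA	0.3
max_loop	NA	NA	30
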