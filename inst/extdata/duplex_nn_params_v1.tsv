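# mircnn duplex nearest-neighbor parameter set, version 1
# kind=scalar rows: global terms (kcal/mol or kcal/mol per nt)
# kind=stack rows: name is 5'XY3'/3'WZ5' (X pairs W, Y pairs Z);
#   the loader also applies the strand-swap identity XY/WZ == ZW/YX.
# Watson-Crick values follow the published 10-parameter nearest-neighbor
# set for RNA at 37 C; G:U wobble stacks are approximate Turner-style
# values, with tandem-wobble stacks floored at -0.30 so that every
# canonical stack is stabilizing (a simplification of this model).
kind	name	value
scalar	duplex_init	4.09
scalar	loop_base	3.0
scalar	loop_per_nt	0.35
stack	AA/UU	-0.93
stack	AU/UA	-1.10
stack	UA/AU	-1.33
stack	CU/GA	-2.08
stack	CA/GU	-2.11
stack	GU/CA	-2.24
stack	GA/CU	-2.35
stack	CG/GC	-2.36
stack	GG/CC	-3.26
stack	GC/CG	-3.42
stack	AG/UU	-0.55
stack	AU/UG	-1.36
stack	CG/GU	-1.41
stack	CU/GG	-2.11
stack	GG/CU	-1.53
stack	GU/CG	-2.51
stack	UG/AU	-1.27
stack	UU/AG	-1.00
stack	GG/UU	-0.50
stack	GU/UG	-0.30
stack	UG/GU	-0.30
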