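# RNA:RNA duplex nearest-neighbor free-energy parameters (Turner 1999 set)
# dG at 37C, kcal/mol. stack rows: k1/k2 are consecutive base pairs of an
# antiparallel helix 5'-k1[1] k2[1]-3' / 3'-k1[2] k2[2]-5'. bulge/internal
# rows: k1 is the loop size in unpaired nucleotides. Inf marks a
# disallowed size.
category	k1	k2	value
stack	CG	CG	-3.30
stack	CG	GC	-2.40
stack	CG	GU	-1.40
stack	CG	UG	-2.10
stack	CG	AU	-2.10
stack	CG	UA	-2.10
stack	GC	CG	-3.40
stack	GC	GC	-3.30
stack	GC	GU	-1.50
stack	GC	UG	-2.50
stack	GC	AU	-2.40
stack	GC	UA	-2.20
stack	GU	CG	-2.50
stack	GU	GC	-2.10
stack	GU	GU	-0.50
stack	GU	UG	1.30
stack	GU	AU	-1.30
stack	GU	UA	-1.40
stack	UG	CG	-1.50
stack	UG	GC	-1.40
stack	UG	GU	0.30
stack	UG	UG	-0.50
stack	UG	AU	-1.00
stack	UG	UA	-0.60
stack	AU	CG	-2.20
stack	AU	GC	-2.10
stack	AU	GU	-0.60
stack	AU	UG	-1.40
stack	AU	AU	-0.90
stack	AU	UA	-1.10
stack	UA	CG	-2.40
stack	UA	GC	-2.10
stack	UA	GU	-1.00
stack	UA	UG	-1.30
stack	UA	AU	-1.30
stack	UA	UA	-0.90
bulge	1		3.80
internal	1		Inf
bulge	2		2.80
internal	2		4.10
bulge	3		3.20
internal	3		5.10
bulge	4		3.60
internal	4		1.70
bulge	5		4.00
internal	5		1.80
bulge	6		4.40
internal	6		2.00
bulge	7		4.59
internal	7		2.20
bulge	8		4.70
internal	8		2.30
bulge	9		4.80
internal	9		2.40
bulge	10		4.90
internal	10		2.50
bulge	11		5.00
internal	11		2.60
bulge	12		5.10
internal	12		2.70
bulge	13		5.19
internal	13		2.78
bulge	14		5.27
internal	14		2.86
bulge	15		5.34
internal	15		2.94
bulge	16		5.41
internal	16		3.01
bulge	17		5.48
internal	17		3.07
bulge	18		5.54
internal	18		3.13
bulge	19		5.60
internal	19		3.19
bulge	20		5.65
internal	20		3.25
bulge	21		5.71
internal	21		3.30
bulge	22		5.76
internal	22		3.35
bulge	23		5.80
internal	23		3.40
bulge	24		5.85
internal	24		3.45
bulge	25		5.89
internal	25		3.49
bulge	26		5.94
internal	26		3.53
bulge	27		5.98
internal	27		3.57
bulge	28		6.02
internal	28		3.61
bulge	29		6.05
internal	29		3.65
bulge	30		6.09
internal	30		3.69
misc	duplex_init		4.10
misc	terminal_au		0.50
misc	ninio_m		0.50
misc	ninio_max		3.00
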