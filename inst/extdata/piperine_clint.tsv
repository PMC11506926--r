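# Condition-level in vitro intrinsic clearance of piperine in pooled human
# liver microsomes (substrate-depletion method), uL/min/mg protein.
# Four in-house incubation conditions plus two literature determinations
# (Zabela et al.; Gou et al.), all entering the pooled model input as an
# unweighted mean.
clint_ul_min_mg	protein_mg_ml	substrate_uM	source
33.2	0.33	0.1	in-house
12.9	0.33	1	in-house
34.0	0.5	0.1	in-house
10.6	0.5	1	in-house
10.3	0.5	1	Zabela
44.2	0.5	1	Gou
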