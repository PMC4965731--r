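feature	accuracy	gini_index	combined_score
structural_holes	0.3081	579.9545	13.37
degree	0.3088	578.1108	13.36
coreness	0.3056	474.7823	12.05
k_step_markov	0.2958	371.1454	10.47
subgraph	0.3032	354.3712	10.36
within_module_z	0.2704	291.5019	8.88
katz	0.2882	259.1472	8.64
closeness	0.2943	227.2495	8.18
proximity_prestige	0.2962	222.5109	8.12
eigenvector	0.2834	230.7507	8.09
betweenness	0.2731	230.3441	7.93
barycenter	0.2742	118.4802	5.70
clustering_coefficient	0.0632	0.3585	0.15
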