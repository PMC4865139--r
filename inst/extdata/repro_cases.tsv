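case_id	category	input1	input2	expected	tolerance_pct	note
basal_ratio_A_vs_F	ratio	24.09	4.03	5.96	1	basal efficiency of the weakly folded variant A over the strongly folded variant F; the published 5.96 reflects unrounded assay means
predict_at_0	predict	trb1_primary	0	127.29	0.01	prefactor check: prediction at dG = 0 equals a exactly
predict_at_control_leader	predict	trb1_primary	-6.8	107.5362444	0.5	prediction at the control leader folding energy
predict_at_variant_A	predict	trb1_primary	-69.0	22.99479642	0.5	prediction at the variant A folding energy
predict_at_variant_G	predict	trb1_primary	-127.0	5.456829524	0.5	prediction at the variant G folding energy
predict_at_variant_F	predict	trb1_primary	-128.9	5.205667562	0.5	prediction at the variant F folding energy
recover_a	recover	a	NA	127.29	1e-8	noiseless exponential data must return the generating prefactor
recover_b	recover	b	NA	0.0248	1e-8	noiseless exponential data must return the generating exponent
model_potential_A_vs_F	potential	-69.0	-128.9	4.417261792	0.5	closed-form predicted potential exp(b * (X_ref - X_var)) under trb1_primary
fold_change_dG1_dG8_A	reference_only	NA	NA	28.1	NA	wet-lab fold change (coupled transcription-translation); not computable in silico
fold_change_dG1_dG8_F	reference_only	NA	NA	55.8	NA	wet-lab fold change; not computable in silico
fold_change_p16_combo	reference_only	NA	NA	12.30	NA	wet-lab fold change for the CDKN2A 5'UTR construct; not computable in silico
fold_change_dG10_cells	reference_only	NA	NA	4.8	NA	wet-lab fold change in cells; not computable in silico
r_squared_full_series	reference_only	NA	NA	0.9746	NA	needs the full seven-variant efficiency table, which is not distributed with the study text
dg_variant_A	reference_only	NA	NA	-69.0	NA	folding energy from a specific external engine and the real variant A sequence; treated as given input, not as a folding-engine target
dg_variant_G	reference_only	NA	NA	-127.0	NA	folding energy treated as given input (see dg_variant_A)
dg_variant_F	reference_only	NA	NA	-128.9	NA	folding energy treated as given input (see dg_variant_A)
dg_control_leader	reference_only	NA	NA	-6.8	NA	folding energy treated as given input (see dg_variant_A)
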