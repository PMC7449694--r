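sex	exposure	outcome	adjusted_for	method	n_snps	measure	est	ci_low	ci_high
male	statin_mimic	ihd	none	ivw	1	or	0.55	0.38	0.79
female	statin_mimic	ihd	none	ivw	1	or	0.87	0.59	1.27
male	testosterone	ihd	none	ivw	125	or	1.11	1.04	1.19
female	testosterone	ihd	none	ivw	254	or	0.96	0.89	1.03
male	statin_mimic	ihd	testosterone	mvmr_ivw	126	or	1.05	0.74	1.47
male	statin_mimic	ihd	testosterone	mvmr_egger	126	or	0.73	0.48	1.11
female	statin_mimic	ihd	testosterone	mvmr_egger	255	or	0.72	0.55	0.94
male	testosterone	ihd	statin_mimic	mvmr_ivw	126	or	1.11	1.04	1.20
female	testosterone	ihd	statin_mimic	mvmr_ivw	255	or	0.96	0.90	1.04
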