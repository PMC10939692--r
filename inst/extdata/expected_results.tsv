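outcome	ivw_estimate	ivw_se	ivw_ci_low	ivw_ci_high	ivw_p	q	q_p	wm_estimate	wm_se	wm_ci_low	wm_ci_high	wm_p	egger_estimate	egger_se	egger_ci_low	egger_ci_high	egger_p	egger_intercept	egger_intercept_se	egger_intercept_ci_low	egger_intercept_ci_high	egger_intercept_p
FN-BMD	0.406	0.176	0.061	0.751	0.021	5.795	0.447	0.519	0.233	0.062	0.976	0.026	1.140	0.700	−0.231	2.512	0.103	−0.014	0.013	−0.039	0.011	0.278
FA-BMD	0.27	0.283	−0.285	0.825	0.340	6.480	0.840	0.228	0.370	−0.496	0.953	0.537	−0.431	1.333	−3.044	2.182	0.746	0.013	0.024	−0.034	0.060	0.590
LS-BMD	0.369	0.253	−0.128	0.866	0.145	9.143	0.166	0.150	0.273	−0.385	0.684	0.583	−0.267	1.062	−2.350	1.815	0.801	0.012	0.019	−0.026	0.050	0.536
HE-BMD	0.001	0.176	−0.344	0.346	0.995	105.854	<.0001	−0.083	0.077	−0.234	0.069	0.285	−0.655	0.684	−1.997	0.686	0.338	0.013	0.013	−0.013	0.038	0.321
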