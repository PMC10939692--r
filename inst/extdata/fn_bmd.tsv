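rsid	beta_exp	se_exp	beta_out	se_out
rs301800	0.019111853	0.0034	0.014618	0.009739
rs11210860	0.017102334	0.0027	0.008337	0.007788
rs34305371	0.035468014	0.005	0.022214	0.013248
rs1008078	−0.016495697	0.0026	−0.000474	0.007677
rs1777827	0.01502804	0.0027	−0.00236	0.007657
rs2992632	0.016756467	0.0029	0.018047	0.008312
rs11689269	0.015776847	0.0028	−0.002428	0.008026
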