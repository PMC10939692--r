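rsid	beta_exp	se_exp	beta_out	se_out
rs301800	0.019111853	0.0034	0.030694	0.011341
rs11210860	0.017102334	0.0027	−0.002349	0.009091
rs34305371	0.035468014	0.005	−0.000976	0.015432
rs1008078	−0.016495697	0.0026	0.004887	0.008914
rs1777827	0.01502804	0.0027	0.011365	0.008923
rs2992632	0.016756467	0.0029	0.004959	0.009714
rs11689269	0.015776847	0.0028	0.015661	0.009369
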