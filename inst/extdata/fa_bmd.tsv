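rsid	beta_exp	se_exp	beta_out	se_out
rs301800	0.019111853	0.0034	0.019201	0.020404
rs11210860	0.017102334	0.0027	0.011222	0.016369
rs34305371	0.035468014	0.005	0.0078	0.026578
rs1008078	−0.016495697	0.0026	−0.003892	0.01571
rs11588857	0.019843614	0.0032	−0.007333	0.018913
rs1777827	0.01502804	0.0027	0.002948	0.01609
rs2992632	0.016756467	0.0029	−0.012144	0.017286
rs76076331	0.020480903	0.0036	−0.030386	0.022883
rs11689269	0.015776847	0.0028	0.002264	0.016959
rs11690172	0.014891586	0.0027	0.020893	0.016269
rs2457660	−0.016828016	0.0028	−0.011393	0.015803
rs10496091	−0.017826263	0.0029	−0.019385	0.017271
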