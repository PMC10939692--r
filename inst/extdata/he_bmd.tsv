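rsid	beta_exp	se_exp	beta_out	se_out
rs301800	0.019111853	0.0034	0.0200508	0.00241906
rs11210860	0.017102334	0.0027	0.00249778	0.00188731
rs34305371	0.035468014	0.005	−0.0147257	0.00302308
rs1008078	−0.016495697	0.0026	−0.00321085	0.0018774
rs11588857	0.019843614	0.0032	−0.00164935	0.00224865
rs1777827	0.01502804	0.0027	−0.00123398	0.00187357
rs2992632	0.016756467	0.0029	−0.00567569	0.00203533
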