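rsid	chrom	pos	effect_allele	eaf	beta	se	pvalue	n
rs301800	1	8490603	T	0.1807	0.01911185	.0034	1.794E−08	293,723
rs11210860	1	43982527	A	0.3721	0.01710233	.0027	2.359E−10	293,723
rs34305371	1	72733610	A	0.0939	0.03546801	.005	3.762E−14	293,723
rs1008078	1	91189731	T	0.4057	−0.0164957	.0026	6.005E−10	293,723
rs11588857	1	204587047	A	0.2115	0.01984361	.0032	5.272E−10	293,723
rs1777827	1	211613114	A	0.5942	0.01502804	.0027	1.547E−08	293,723
rs2992632	1	243503764	A	0.7177	0.01675647	.0029	8.227E−09	293,723
rs76076331	2	10977585	T	0.1463	0.0204809	.0036	3.632E−08	293,723
rs11689269	2	15621917	C	0.3346	0.01577685	.0028	1.283E−08	293,723
rs11690172	2	57387094	A	0.5903	0.01489159	.0027	1.994E−08	293,723
rs2457660	2	60757419	T	0.6354	−0.01682802	.0028	7.107E−10	293,723
rs10496091	2	61482261	A	0.2902	−0.01782626	.0029	5.615E−10	293,723
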