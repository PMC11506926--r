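# Human tissue composition for mechanistic (Rodgers-Rowland method 2)
# tissue:plasma-water partitioning.
# Fractional water/lipid contents and acidic phospholipid (AP) concentrations
# are the published rat-derived Rodgers-Rowland dataset, applied to humans as
# is standard practice in open PBPK implementations (no equivalent measured
# human set exists).  volume_frac are adult human fractional tissue volumes
# (L per kg body weight, ICRP-style reference man: muscle 0.40, adipose
# 0.2142, blood 0.0771 of which plasma 0.0424 / erythrocytes 0.0347).
# "rest" is a lumped remainder compartment (total body volume ~1 L/kg) given
# muscle-like composition.  ph_iw: intracellular water pH (7.0 for tissues,
# 7.22 for erythrocytes).  ap in mg/g tissue.
tissue	f_ew	f_iw	f_nl	f_np	ap	ph_iw	volume_frac
adipose	0.135	0.017	0.853	0.0016	0.40	7.0	0.2142
bone	0.100	0.346	0.017	0.0017	0.67	7.0	0.0856
brain	0.162	0.620	0.039	0.0015	0.40	7.0	0.0200
gut	0.282	0.475	0.038	0.0125	2.41	7.0	0.0171
heart	0.320	0.456	0.014	0.0111	2.25	7.0	0.0047
kidney	0.273	0.483	0.012	0.0242	5.03	7.0	0.0044
liver	0.161	0.573	0.014	0.0240	4.56	7.0	0.0257
lung	0.336	0.446	0.022	0.0128	3.91	7.0	0.0076
muscle	0.118	0.630	0.010	0.0072	1.53	7.0	0.4000
skin	0.382	0.291	0.060	0.0044	1.32	7.0	0.0371
spleen	0.207	0.579	0.0077	0.0113	3.18	7.0	0.0026
rest	0.118	0.630	0.010	0.0072	1.53	7.0	0.0830
blood_cells	0.000	0.603	0.0017	0.0029	0.50	7.22	0.0347
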