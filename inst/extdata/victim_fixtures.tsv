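# SYNTHETIC victim-drug parameter table for CYP3A4 interaction simulation.
# The simulation platform used in the source clinical-modeling literature
# ships unpublished built-in victim compound files; this table is an openly
# documented stand-in assembled once from standard literature PK constants.
# Columns:
#   dose_mg        oral single dose used in the interaction scenario
#   mw             g/mol
#   fu_plasma      fraction unbound in plasma
#   bp_ratio       blood:plasma concentration ratio
#   vss_lkg        steady-state volume of distribution, L/kg
#   ka_h           first-order oral absorption rate constant, 1/h
#   cl_plasma_lh   systemic plasma clearance, L/h (well-stirred hepatic
#                  unbound CLint is back-calculated from this; any renal
#                  component is folded into the non-CYP3A4 fraction)
#   fm_cyp3a4      fraction of systemic clearance mediated by CYP3A4
#   fg_baseline    baseline intestinal availability (gut CYP3A4 CLint is
#                  back-calculated through the Qgut model with fu_gut = 1)
#   qgut_lh        Qgut hybrid flow, L/h
# Provenance (typical literature values): midazolam fu 0.032, B/P 0.66,
# CL ~27 L/h, fm_CYP3A4 0.94, Fg 0.57 (Gertz/Galetin IVIVE datasets);
# simvastatin lactone fm ~0.99, extensive gut first pass (low Fg);
# carbamazepine low-extraction, CYP3A4 share of net clearance ~0.55,
# negligible gut extraction; triazolam/alfentanil/nifedipine/cyclosporine
# per standard DDI-modeling compilations.  Values are fixed study
# conditions of this package, not fitted quantities.
name	dose_mg	mw	fu_plasma	bp_ratio	vss_lkg	ka_h	cl_plasma_lh	fm_cyp3a4	fg_baseline	qgut_lh
carbamazepine	400	236.27	0.25	1.07	1.2	0.5	3.7	0.55	0.98	15.7
clarithromycin	250	747.95	0.30	1.00	2.6	1.0	22.0	0.60	0.87	15.7
midazolam	5	325.77	0.032	0.66	1.0	3.0	27.0	0.94	0.57	15.7
itraconazole	200	705.63	0.036	0.58	4.0	0.4	20.0	0.95	0.90	15.7
ritonavir	100	720.94	0.015	0.60	0.41	0.8	8.0	0.75	0.85	15.7
nifedipine	20	346.33	0.04	0.70	0.78	2.0	30.0	0.78	0.75	15.7
cyclosporine	200	1202.6	0.07	1.36	1.3	0.7	23.0	0.85	0.66	15.7
triazolam	0.25	343.21	0.10	0.78	1.1	2.5	11.0	0.92	0.70	15.7
alfentanil	0.043	416.52	0.10	0.63	0.5	3.0	18.0	0.93	0.60	15.7
simvastatin	40	418.57	0.05	0.64	2.0	1.5	35.0	0.99	0.34	15.7
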