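# Observed piperine pharmacokinetics in Chinese healthy volunteers
# (Wang et al. clinical study): 20 mg oral single dose and 20 mg/day for
# 7 consecutive days.  Used as the validation comparator set.
metric	value	sd
single_cmax_ng_ml	290	15
single_auc_ng_ml_h	5642	338
multiple_cmax_ng_ml	595	39
multiple_auc_ng_ml_h	14356	1365
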