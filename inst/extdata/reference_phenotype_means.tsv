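trait	control_mean	control_se	stress_mean	stress_se	difference	difference_se
dfi	2.79	0.07	2.44	0.08	0.35	0.11
adg	1.33	0.03	1.11	0.03	0.21	0.04
fcr	2.11	0.05	2.23	0.05	-0.12	0.07
cortisol_auc	192.49	16.55	299.62	16.55	-107.13	23.40
lesion_score	44.42	7.00	104.11	7.05	-59.69	9.93
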