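model	raw_weight	max_abs_weight
rf	30	60
svm	-22	88
lasso	20	80
nn	-2	8
gbm	320	640
dt	-8	16
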