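metric,raw_features,presegmented
per_class_accuracy_pct,54.3,70.4
quadratic_weighted_kappa,0.85,0.90
macro_auc,0.88,0.92
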