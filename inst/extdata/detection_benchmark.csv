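annotator,metric,MA,HEM,CWS,HE,PC,IRMA,NV
model,precision,0.66,0.59,0.38,0.63,0.82,0.41,0.40
model,recall,0.67,0.74,0.46,0.61,0.84,0.67,0.77
model,f1,0.66,0.66,0.42,0.62,0.83,0.51,0.53
expert2,precision,0.73,0.57,0.75,0.70,0.90,0.54,0.45
expert2,recall,0.47,0.68,0.41,0.71,0.85,0.40,0.88
expert2,f1,0.57,0.62,0.53,0.70,0.87,0.46,0.60
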