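split,MA,HEM,PC,HE,CWS,IRMA,NV
training,11024,2622,7148,2357,385,846,157
tuning,1840,552,1535,338,76,220,23
testing,2018,452,1676,348,93,335,30
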