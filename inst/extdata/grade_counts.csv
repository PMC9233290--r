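split,level0,level1,level2,level3,level4
training,11926,2863,4797,1490,2367
tuning,1595,369,632,191,392
testing,2361,575,797,310,660
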