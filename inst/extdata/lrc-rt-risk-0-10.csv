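i,time,lower,upper,nrisk
1,0,1,30,213
2,10,31,31,122
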