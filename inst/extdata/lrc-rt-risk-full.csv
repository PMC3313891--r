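i,time,lower,upper,nrisk
1,0,1,30,213
2,10,31,58,122
3,20,59,83,80
4,30,84,102,51
5,40,103,120,30
6,50,121,128,10
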