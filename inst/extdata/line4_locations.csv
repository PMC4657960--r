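id,x,y,population
L0,0,0,10
L1,1,0,20
L2,2,0,30
L3,3,0,40
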