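origin,destination,trips
L0,L1,566
L0,L2,271
L0,L3,163
L1,L0,335
L1,L2,476
L1,L3,189
L2,L0,79
L2,L1,416
L2,L3,505
L3,L0,171
L3,L1,276
L3,L2,553
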