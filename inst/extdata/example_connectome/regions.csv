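label,hemisphere
L1,left
L2,left
L3,left
L4,left
R1,right
R2,right
R3,right
R4,right
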