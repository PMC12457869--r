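participant,day,beep,value
P0001,0,0,42
P0001,0,1,55.5
P0002,3,2,0
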