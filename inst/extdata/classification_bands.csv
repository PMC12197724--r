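index,lower,upper,label
PI,0,1,unpolluted
PI,1,2,mild
PI,2,3,moderate
PI,3,Inf,heavy
PN,0,0.7,safe
PN,0.7,1,warning
PN,1,2,light
PN,2,3,moderate
PN,3,Inf,heavy
Igeo,-Inf,0,unpolluted
Igeo,0,1,light
Igeo,1,2,moderate
Igeo,2,3,moderate-heavy
Igeo,3,4,heavy
Igeo,4,5,heavy-extreme
Igeo,5,Inf,extreme
Er,0,40,low
Er,40,80,moderate
Er,80,160,considerable
Er,160,320,high
Er,320,Inf,very high
RI,0,80,low
RI,80,160,moderate
RI,160,320,considerable
RI,320,Inf,high
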