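metal,background,toxic_response
As,20,10
Cd,0.66,30
Cr,95.9,2
Hg,0.1,40
Pb,35.2,5
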