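variable,min,max,mean,sd
As,1.19,24.87,9.08,5.38
Cd,0.08,0.75,0.36,0.16
Cr,15.97,149.82,73.06,29.21
Hg,0.02,0.29,0.13,0.06
Pb,11.42,49.38,28.14,8.09
pH,3.84,8.06,6.14,0.96
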