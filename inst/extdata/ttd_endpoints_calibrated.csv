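metal,organ,ttd
As,neurological,3.2392e-4
As,renal,9.0696e-4
As,cardiovascular,3.2392e-4
As,hematological,1.2957e-3
As,testicular,4.5348e-3
Cd,renal,2.3973e-4
Cd,hematological,3.5959e-4
Cd,testicular,7.1918e-4
Cr,neurological,2.4326e-2
Cr,renal,1.6217e-2
Cr,cardiovascular,1.2163e-2
Cr,hematological,2.6063e-3
Cr,testicular,6.3458e-3
Pb,neurological,1.3385e-3
Pb,renal,7.2072e-4
Pb,cardiovascular,2.3423e-3
Pb,hematological,1.1243e-3
Pb,testicular,9.3693e-3
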