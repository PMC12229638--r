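element,mass
H,1.0078250319
C,12.0000000000
N,14.0030740052
O,15.9949146221
F,18.9984031627
Na,22.9897692820
P,30.9737615120
S,31.9720706912
Cl,34.9688527100
K,38.9637064864
Br,78.9183376000
I,126.9044719300
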