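element,monoisotopic,average
C,12.0000000,12.0107
H,1.0078250,1.00794
N,14.0030740,14.0067
O,15.9949146,15.9994
S,31.9720707,32.065
P,30.9737615,30.973762
Cl,34.9688527,35.453
Na,22.9897693,22.989770
K,38.9637064,39.0983
Fe,55.9349421,55.845
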