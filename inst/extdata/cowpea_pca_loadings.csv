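trait,PC1,PC2,PC3,PC4,PC5
DFF,0.26,0.49,-0.35,-0.32,-0.46
DNPM,0.27,0.38,-0.53,0.25,0.62
PHM,0.24,0.35,0.65,-0.38,0.35
NPP,0.40,-0.30,0.18,0.30,0.27
PODWT,0.43,-0.29,-0.03,-0.06,-0.16
NSP,0.44,-0.16,-0.08,-0.52,0.05
GWT,0.43,-0.30,-0.09,0.19,-0.21
HSW,0.28,0.45,0.34,0.54,-0.36
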