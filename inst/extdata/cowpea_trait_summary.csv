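trait,grand_mean,grand_sd,lsd_05,cv_pct
DFF,40.37,2.37,1.44,3.9
DNPM,64.74,2.22,1.04,1.7
PHM,29.20,5.98,2.04,3.4
NPP,20.77,5.98,2.64,13.7
PODWT,2.50,0.39,0.21,9.0
NSP,13.55,1.46,1.16,9.2
GWT,1.70,1.42,0.12,7.7
HSW,17.50,0.26,0.57,3.5
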