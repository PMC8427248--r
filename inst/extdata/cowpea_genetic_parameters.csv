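trait,var_e,var_g,var_p,h2,gcv,pcv,ga,gam
DFF,2.68,9.35,12.03,77.72,7.57,8.59,5.56,13.78
DNPM,1.32,11.35,12.67,89.58,5.20,5.50,6.58,10.16
PHM,16.68,60.92,77.60,78.51,26.73,30.17,14.27,48.86
NPP,9.59,45.01,54.60,82.44,32.30,35.58,12.57,60.51
PODWT,0.07,0.26,0.33,78.79,20.40,22.98,0.93,37.35
NSP,1.55,1.90,3.45,55.03,10.16,13.70,2.11,15.55
GWT,0.02,0.13,0.15,86.36,20.94,22.53,0.68,40.14
HSW,0.46,4.97,5.43,91.52,12.73,13.31,4.40,25.13
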