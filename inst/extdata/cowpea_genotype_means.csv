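genotype,trait,mean,sd
IT07K-299-6,DFF,41.78,1.41
IT07K-299-6,DNPM,64.44,0.29
IT07K-299-6,PHM,30.56,1.36
IT07K-299-6,NPP,25.11,4.34
IT07K-299-6,PODWT,2.77,0.30
IT07K-299-6,NSP,14.78,1.23
IT07K-299-6,GWT,1.91,0.20
IT07K-299-6,HSW,16.80,0.70
IT08K-125-107,DFF,41.22,0.86
IT08K-125-107,DNPM,63.56,1.18
IT08K-125-107,PHM,37.00,7.80
IT08K-125-107,NPP,14.33,6.44
IT08K-125-107,PODWT,1.68,0.80
IT08K-125-107,NSP,11.78,1.77
IT08K-125-107,GWT,1.16,0.50
IT08K-125-107,HSW,18.47,0.90
IT10K-836-2,DFF,41.56,1.19
IT10K-836-2,DNPM,64.33,0.41
IT10K-836-2,PHM,24.22,4.97
IT10K-836-2,NPP,21.11,0.34
IT10K-836-2,PODWT,2.39,0.10
IT10K-836-2,NSP,12.78,0.77
IT10K-836-2,GWT,1.78,0.10
IT10K-836-2,HSW,18.87,1.30
Songotra,DFF,42.11,1.57
Songotra,DNPM,64.67,0.07
Songotra,PHM,30.00,0.80
Songotra,NPP,19.42,1.35
Songotra,PODWT,2.43,0.01
Songotra,NSP,13.67,0.12
Songotra,GWT,1.68,0.01
Songotra,HSW,16.64,0.90
SARI-2-2-1,DFF,39.56,0.81
SARI-2-2-1,DNPM,62.56,2.18
SARI-2-2-1,PHM,30.11,0.92
SARI-2-2-1,NPP,15.78,4.99
SARI-2-2-1,PODWT,2.44,0.11
SARI-2-2-1,NSP,13.33,0.22
SARI-2-2-1,GWT,1.52,0.20
SARI-2-2-1,HSW,16.74,0.80
SARI-2-3-4,DFF,40.89,0.52
SARI-2-3-4,DNPM,65.56,0.82
SARI-2-3-4,PHM,21.44,7.75
SARI-2-3-4,NPP,12.00,8.77
SARI-2-3-4,PODWT,1.96,0.50
SARI-2-3-4,NSP,13.11,0.44
SARI-2-3-4,GWT,1.40,0.30
SARI-2-3-4,HSW,16.37,1.20
SARI-3-11-100,DFF,43.11,2.75
SARI-3-11-100,DNPM,67.22,2.48
SARI-3-11-100,PHM,40.89,11.69
SARI-3-11-100,NPP,25.20,4.43
SARI-3-11-100,PODWT,2.87,0.40
SARI-3-11-100,NSP,15.22,1.67
SARI-3-11-100,GWT,1.99,0.30
SARI-3-11-100,HSW,21.27,3.70
SARI-3-11-45,DFF,40.56,0.19
SARI-3-11-45,DNPM,66.56,1.82
SARI-3-11-45,PHM,32.33,3.14
SARI-3-11-45,NPP,21.24,0.47
SARI-3-11-45,PODWT,2.61,0.20
SARI-3-11-45,NSP,13.89,0.34
SARI-3-11-45,GWT,1.77,0.10
SARI-3-11-45,HSW,18.25,0.70
SARI-3-11-80,DFF,39.44,0.92
SARI-3-11-80,DNPM,65.56,0.82
SARI-3-11-80,PHM,31.78,2.58
SARI-3-11-80,NPP,22.42,1.65
SARI-3-11-80,PODWT,2.42,0.12
SARI-3-11-80,NSP,13.44,0.10
SARI-3-11-80,GWT,1.71,0.02
SARI-3-11-80,HSW,18.82,1.30
SARI-3-11-90,DFF,42.00,1.63
SARI-3-11-90,DNPM,67.00,2.26
SARI-3-11-90,PHM,26.33,2.86
SARI-3-11-90,NPP,20.51,0.26
SARI-3-11-90,PODWT,2.55,0.10
SARI-3-11-90,NSP,14.00,0.45
SARI-3-11-90,GWT,1.75,0.10
SARI-3-11-90,HSW,17.55,0.01
SARI-5-5-5,DFF,37.11,3.25
SARI-5-5-5,DNPM,59.78,4.96
SARI-5-5-5,PHM,28.44,0.75
SARI-5-5-5,NPP,24.60,3.83
SARI-5-5-5,PODWT,2.65,0.20
SARI-5-5-5,NSP,13.78,0.23
SARI-5-5-5,GWT,1.80,0.10
SARI-5-5-5,HSW,16.86,0.70
SARI-6-2-6,DFF,43.33,2.97
SARI-6-2-6,DNPM,68.33,3.60
SARI-6-2-6,PHM,29.00,0.20
SARI-6-2-6,NPP,24.33,3.56
SARI-6-2-6,PODWT,2.81,0.40
SARI-6-2-6,NSP,14.00,0.45
SARI-6-2-6,GWT,1.88,0.20
SARI-6-2-6,HSW,18.18,0.70
SARI-6-2-9,DFF,37.56,2.81
SARI-6-2-9,DNPM,63.33,1.41
SARI-6-2-9,PHM,23.33,5.86
SARI-6-2-9,NPP,16.27,4.50
SARI-6-2-9,PODWT,2.13,0.30
SARI-6-2-9,NSP,12.00,1.55
SARI-6-2-9,GWT,1.51,0.20
SARI-6-2-9,HSW,16.33,1.20
SARVX-09-001,DFF,38.44,1.92
SARVX-09-001,DNPM,63.78,0.96
SARVX-09-001,PHM,27.67,1.53
SARVX-09-001,NPP,20.29,0.48
SARVX-09-001,PODWT,2.55,0.10
SARVX-09-001,NSP,13.00,0.55
SARVX-09-001,GWT,1.72,0.02
SARVX-09-001,HSW,16.76,0.80
SARVX-09-002,DFF,39.33,1.03
SARVX-09-002,DNPM,64.78,0.04
SARVX-09-002,PHM,27.22,1.97
SARVX-09-002,NPP,23.11,2.34
SARVX-09-002,PODWT,2.37,0.10
SARVX-09-002,NSP,13.56,0.01
SARVX-09-002,GWT,1.71,0.02
SARVX-09-002,HSW,16.60,0.90
SARVX-09-003,DFF,38.78,1.59
SARVX-09-003,DNPM,64.44,0.29
SARVX-09-003,PHM,28.11,1.08
SARVX-09-003,NPP,23.80,3.30
SARVX-09-003,PODWT,2.34,0.10
SARVX-09-003,NSP,13.33,0.22
SARVX-09-003,GWT,1.63,0.10
SARVX-09-003,HSW,16.61,0.90
SARVX-09-004,DFF,39.44,0.92
SARVX-09-004,DNPM,64.67,0.07
SARVX-09-004,PHM,27.89,1.31
SARVX-09-004,NPP,23.58,2.81
SARVX-09-004,PODWT,2.71,0.30
SARVX-09-004,NSP,14.67,1.12
SARVX-09-004,GWT,1.95,0.30
SARVX-09-004,HSW,16.81,0.70
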