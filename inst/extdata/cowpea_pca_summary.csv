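component,eigenvalue,variability_pct,cumulative_pct
PC1,4.17,52.12,52.12
PC2,1.91,23.89,76.01
PC3,1.03,12.85,88.86
PC4,0.38,4.74,93.60
PC5,0.22,2.77,96.37
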