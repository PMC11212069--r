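trait,water_regime,grand_mean,grand_sem,cv_pct,lsd
RWC,WS,74.27,0.79,14.05,3.45
RWC,WD,10.46,0.54,68.05,7.12
Phi2,WS,0.36,0.01,35.25,0.104
Phi2,WD,0.18,0.01,44.05,0.082
PhiNPQ,WS,0.60,0.01,24.06,0.16
PhiNPQ,WD,0.77,0.01,13.48,0.10
SPAD,WS,37.14,0.38,13.53,3.46
SPAD,WD,5.44,0.30,73.89,2.31
FvFm,WS,0.41,0.01,28.91,0.14
FvFm,WD,0.23,0.00,39.76,0.27
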