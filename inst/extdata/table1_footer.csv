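trait,water_regime,grand_mean,grand_sem,cv_pct,lsd
PH,WS,14.9,0.44,38.0,0.76
PH,WD,8.37,0.22,34.7,0.79
NT,WS,5.07,0.21,53.70,1.13
NT,WD,3.85,0.17,59.3,0.85
NL,WS,4.82,0.09,24.5,1.25
NL,WD,3.39,0.07,26.6,0.95
RL,WS,75.53,1.27,22.3,5.94
RL,WD,51.72,1.09,27.8,17.31
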