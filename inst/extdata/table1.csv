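ecotype,PH_WS_mean,PH_WS_sem,PH_WD_mean,PH_WD_sem,NT_WS_mean,NT_WS_sem,NT_WD_mean,NT_WD_sem,NL_WS_mean,NL_WS_sem,NL_WD_mean,NL_WD_sem,RL_WS_mean,RL_WS_sem,RL_WD_mean,RL_WD_sem
CIAT16449,8.66,0.21,5.6,0.25,2.6,0.60,1.4,0.25,4.4,0.40,2.8,0.37,54.8,0.20,44.4,2.25
CIAT16514,25.04,0.16,10.4,0.25,4.6,0.25,6.2,0.37,4.2,0.37,3.2,0.80,90.8,0.20,42.4,5.06
CIAT6384,11.00,0.32,8.4,0.25,3.0,0.45,2.8,0.37,5.4,0.51,2.8,0.37,85.0,1.67,57.4,5.99
CIAT6385,8.60,0.25,7.8,0.26,1.2,0.20,2.0,0.00,3.2,0.20,3.0,0.45,111.2,0.58,55.2,13.9
CIAT6399,17.46,0.16,4.6,0.25,7.2,0.20,5.0,0.32,5.4,0.40,2.6,0.25,90.6,0.25,48.2,4.74
CIAT6426,15.7,0.26,6.5,0.22,2.2,0.49,1.8,0.37,4.4,0.24,3.2,0.20,76.6,0.93,49.2,6.06
CIAT6684,10.82,0.23,9.0,0.27,3.0,0.00,1.2,0.20,4.2,0.74,3.2,0.20,51.0,0.45,47.8,3.18
Basilisk,18.5,0.22,7.8,0.30,11.8,0.20,4.8,0.20,5.8,0.37,2.8,0.20,79.6,4.89,57.0,4.09
Busia,13.9,0.19,7.9,0.18,7.6,0.25,6.6,0.25,6.2,0.49,4.0,0.00,55.4,0.25,54.8,5.42
K1,24.1,0.40,11.5,0.32,4.6,0.25,3.4,0.40,5.8,0.37,4.6,0.40,80.0,0.32,43.4,4.28
K2,16.60,0.37,12.2,0.52,6.6,0.25,6.8,0.37,4.4,0.25,2.8,0.37,77.0,0.45,43.6,9.41
K3,12.8,0.12,11.0,0.61,3.2,0.20,2.0,0.32,4.0,0.32,4.4,0.40,74.4,0.25,53.2,7.08
K4,15.46,0.17,11.6,0.29,3.4,0.25,2.4,0.25,4.2,0.37,3.6,0.25,82.0,0.00,50.2,6.64
K5,12.56,0.25,5.2,0.20,2.8,0.20,1.4,0.25,4.0,0.32,2.4,0.40,50.6,0.40,55.0,1.48
K6,18.00,0.27,6.4,0.25,4.2,0.86,5.0,0.32,5.2,0.92,3.0,0.45,72.6,4.37,53.0,4.72
K7,29.90,0.33,12.5,0.22,6.6,0.25,3.8,0.20,5.2,0.58,4.2,0.20,87.2,0.37,62.6,3.47
K8,12.54,0.23,6.6,0.25,5.0,0.71,4.2,0.20,6.0,0.55,2.8,0.20,97.0,0.55,51.0,2.30
K9,11.54,0.25,6.5,0.32,2.8,0.20,2.2,0.37,5.0,0.55,2.8,0.49,121.8,6.21,53.0,11.6
K10,22.0,0.55,7.6,0.25,5.6,0.25,4.4,0.25,5.8,0.37,3.6,0.40,68.2,0.49,69.2,4.22
K12,16.3,0.37,7.7,9.20,3.8,0.20,1.4,0.25,4.2,0.20,3.6,0.25,87.4,0.40,42.0,3.89
K13,7.08,0.11,5.2,0.37,2.2,0.20,2.2,0.20,4.6,0.25,2.8,0.37,53.0,6.20,55.4,8.62
K15,7.64,0.09,4.6,0.19,7.2,0.20,9.0,0.00,4.8,0.58,4.6,0.40,55.6,0.25,50.6,5.62
K16,11.62,0.18,8.8,0.12,3.0,0.71,2.0,0.45,4.8,0.66,3.2,0.49,84.8,1.24,49.0,7.63
K17,21.20,0.37,15.8,0.26,5.8,0.20,4.2,0.37,4.6,0.25,4.0,0.32,71.8,3.81,62.0,6.31
K18,14.72,0.19,5.7,0.30,4.0,0.00,1.6,0.45,5.0,0.32,3.4,0.25,68.6,0.25,63.2,10.9
K19,17.50,0.22,11.5,0.32,8.4,0.25,3.2,0.37,5.6,0.25,3.6,0.25,75.2,0.37,52.6,6.53
K20,7.80,0.20,6.4,0.25,2.4,0.25,1.8,0.37,5.0,0.32,3.8,0.37,62.2,0.20,53.6,8.39
K21,19.60,0.25,11.6,0.25,3.4,0.25,2.8,0.20,4.0,0.32,3.2,0.20,74.4,0.25,45.8,4.45
K22,24.50,0.22,11.6,0.25,5.0,0.95,5.2,0.20,5.6,0.25,3.4,0.25,58.4,0.25,47.8,2.60
K23,8.12,0.20,5.5,0.32,10.6,0.25,9.0,0.32,5.6,0.40,4.2,0.20,61.4,1.66,63.6,7.35
Kakamega,11.20,0.52,8.6,0.19,5.6,0.25,4.8,0.37,3.6,0.25,3.0,0.00,85.4,1.86,47.6,2.50
Kisii,11.90,0.19,6.8,0.26,11.6,0.40,9.0,0.32,5.2,0.37,3.6,0.25,69.0,0.20,42.2,1.24
Lanet,20.00,0.35,13.0,0.16,6.6,0.25,3.8,0.37,5.6,0.25,4.2,0.20,95.2,0.74,44.6,4.52
Piata,6.40,0.29,4.6,0.25,4.2,0.20,3.0,0.32,4.0,0.95,3.6,0.25,69.8,0.20,36.0,1.26
Toledo,11.0,0.16,6.4,0.24,5.8,0.97,4.2,0.37,3.6,0.40,2.8,0.20,67.4,2.94,63.4,3.41
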