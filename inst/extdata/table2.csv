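ecotype,RWC_WS_mean,RWC_WS_sem,RWC_WD_mean,RWC_WD_sem,Phi2_WS_mean,Phi2_WS_sem,Phi2_WD_mean,Phi2_WD_sem,PhiNPQ_WS_mean,PhiNPQ_WS_sem,PhiNPQ_WD_mean,PhiNPQ_WD_sem,SPAD_WS_mean,SPAD_WS_sem,SPAD_WD_mean,SPAD_WD_sem,FvFm_WS_mean,FvFm_WS_sem,FvFm_WD_mean,FvFm_WD_sem
CIAT16449,81.66,1.60,24.59,1.14,0.45,0.01,0.21,0.03,0.57,0.06,0.74,0.04,43.62,3.02,2.14,0.42,0.43,0.04,0.26,0.03
CIAT16514,73.66,0.44,12.68,0.65,0.33,0.10,0.19,0.04,0.56,0.11,0.75,0.05,33.42,1.90,4.72,0.31,0.44,0.08,0.27,0.05
CIAT6384,68.30,3.41,21.50,13.8,0.56,0.06,0.20,0.03,0.69,0.05,0.75,0.03,36.59,0.81,3.46,0.93,0.50,0.06,0.24,0.03
CIAT6385,75.14,1.08,13.31,1.42,0.42,0.08,0.24,0.04,0.59,0.12,0.69,0.05,26.98,1.22,2.97,0.66,0.48,0.09,0.33,0.04
CIAT6399,89.96,1.69,6.77,0.94,0.37,0.05,0.23,0.04,0.63,0.03,0.71,0.04,37.18,1.03,2.74,0.35,0.45,0.04,0.27,0.03
CIAT6426,70.23,1.12,16.46,0.44,0.45,0.02,0.14,0.02,0.39,0.10,0.82,0.02,37.46,1.32,11.16,1.12,0.46,0.05,0.18,0.02
CIAT6684,72.40,0.66,17.72,0.25,0.17,0.03,0.15,0.02,0.39,0.09,0.81,0.03,43.75,0.86,3.38,0.71,0.32,0.04,0.20,0.03
Basilisk,80.74,0.55,18.10,0.64,0.54,0.02,0.20,0.04,0.70,0.04,0.75,0.03,35.13,0.93,3.13,0.67,0.45,0.05,0.24,0.04
Busia,86.63,0.59,7.09,0.61,0.26,0.01,0.14,0.00,0.64,0.02,0.82,0.01,42.75,0.22,4.12,0.56,0.47,0.04,0.18,0.01
K1,77.73,0.43,9.96,1.38,0.34,0.01,0.12,0.03,0.70,0.04,0.84,0.03,38.41,0.16,13.70,1.02,0.39,0.03,0.17,0.03
K2,93.62,0.89,12.28,0.22,0.53,0.04,0.21,0.01,0.45,0.04,0.72,0.01,38.76,1.66,13.11,0.34,0.46,0.05,0.28,0.01
K3,66.77,0.43,5.08,0.84,0.26,0.02,0.14,0.01,0.56,0.06,0.82,0.02,36.31,0.59,12.08,1.25,0.43,0.01,0.18,0.02
K4,75.62,0.39,16.61,0.61,0.32,0.05,0.12,0.01,0.65,0.04,0.84,0.02,40.54,0.84,6.57,1.86,0.41,0.02,0.19,0.02
K5,64.71,0.43,2.46,0.33,0.30,0.05,0.21,0.02,0.68,0.03,0.74,0.02,34.59,0.19,2.48,0.53,0.38,0.06,0.20,0.02
K6,63.79,0.13,9.65,1.04,0.56,0.06,0.22,0.04,0.71,0.06,0.72,0.03,30.70,1.27,6.66,0.23,0.44,0.09,0.27,0.02
K7,74.35,0.82,9.61,2.21,0.47,0.01,0.11,0.01,0.67,0.06,0.86,0.02,34.51,1.70,12.12,1.00,0.37,0.02,0.15,0.02
K8,76.58,0.54,10.88,1.81,0.40,0.03,0.21,0.01,0.67,0.03,0.73,0.01,32.43,0.88,9.31,0.29,0.47,0.02,0.26,0.01
K9,85.43,0.90,11.56,0.39,0.49,0.04,0.32,0.04,0.51,0.09,0.57,0.05,36.23,0.48,1.92,0.42,0.51,0.03,0.44,0.03
K10,74.18,0.67,8.97,2.31,0.68,0.01,0.19,0.02,0.64,0.04,0.76,0.03,36.45,1.14,2.06,0.37,0.55,0.08,0.25,0.03
K12,62.32,1.05,8.99,1.22,0.45,0.01,0.17,0.02,0.58,0.02,0.78,0.30,33.01,1.50,5.88,0.30,0.42,0.04,0.22,0.03
K13,64.27,2.47,10.0,0.62,0.23,0.01,0.16,0.01,0.72,0.03,0.80,0.02,33.62,0.97,3.13,0.53,0.30,0.04,0.20,0.01
K15,61.32,0.57,5.75,0.65,0.25,0.03,0.16,0.02,0.59,0.06,0.79,0.03,48.48,0.20,1.44,0.16,0.41,0.03,0.21,0.02
K16,74.41,3.36,8.19,0.50,0.24,0.01,0.20,0.05,0.59,0.06,0.74,0.07,34.60,1.17,4.41,1.82,0.36,0.02,0.26,0.05
K17,55.68,1.06,6.74,1.09,0.39,0.02,0.14,0.03,0.66,0.01,0.82,0.04,32.33,0.52,8.33,0.88,0.42,0.04,0.18,0.03
K18,55.68,1.42,3.28,0.81,0.16,0.01,0.15,0.02,0.75,0.04,0.81,0.03,42.10,0.53,3.11,0.37,0.37,0.04,0.19,0.03
K19,64.97,0.91,5.51,0.84,0.23,0.01,0.16,0.03,0.61,0.06,0.79,0.03,36.61,0.52,2.85,0.70,0.28,0.04,0.21,0.03
K20,68.46,1.15,8.94,0.54,0.37,0.05,0.15,0.01,0.41,0.06,0.81,0.01,33.92,0.81,2.94,0.46,0.37,0.06,0.19,0.01
K21,83.73,1.33,13.36,0.42,0.36,0.03,0.17,0.04,0.67,0.03,0.78,0.05,37.14,0.65,11.30,0.46,0.42,0.05,0.23,0.05
K22,68.11,1.39,10.74,1.32,0.27,0.02,0.36,0.09,0.46,0.06,0.52,0.12,36.83,2.07,2.45,0.08,0.38,0.03,0.46,0.09
K23,68.05,0.36,4.18,0.85,0.21,0.02,0.18,0.02,0.55,0.02,0.77,0.03,38.12,2.16,1.45,0.11,0.42,0.05,0.24,0.03
Kakamega,76.20,0.32,6.72,0.53,0.31,0.02,0.16,0.02,0.66,0.03,0.79,0.02,42.09,0.74,5.28,0.71,0.40,0.02,0.21,0.01
Kisii,91.56,1.72,10.67,0.38,0.34,0.04,0.07,0.00,0.52,0.03,0.90,0.00,37.89,0.55,8.12,1.98,0.47,0.01,0.12,0.01
Lanet,71.62,0.29,5.61,1.73,0.37,0.04,0.17,0.02,0.64,0.04,0.78,0.03,33.11,1.80,4.90,0.86,0.34,0.09,0.22,0.02
Piata,88.96,0.22,10.69,1.11,0.25,0.02,0.16,0.01,0.63,0.05,0.80,0.02,45.11,0.53,2.36,0.36,0.26,0.09,0.19,0.01
Toledo,92.97,0.70,11.39,0.23,0.19,0.01,0.23,0.02,0.68,0.03,0.70,0.03,39.37,1.46,4.51,0.85,0.40,0.02,0.31,0.02
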