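meth_dilution,te_dilution,total_ng,ct_col2a1,net_meth_ng,meth_pct,ct_gfra1,gfra1_detection,ct_p16,p16_detection
1,1,18.78,27.90,1.18,6.3,32.82,FULL,33.58,FULL
1/2,1,18.78,28.18,0.59,3.1,33.92,FULL,35.04,FULL
1/4,1,18.78,27.93,0.29,1.6,34.78,FULL,35.13,FULL
1/8,1,18.78,28.18,0.15,0.8,35.84,FULL,36.61,FULL
1/16,1,18.78,28.09,0.07,0.4,37.38,PARTIAL,37.76,FULL
1/32,1,18.78,28.05,0.04,0.2,38.25,PARTIAL,38.49,PARTIAL
1/64,1,18.78,28.10,0.02,0.1,38.99,PARTIAL,38.87,PARTIAL
1,1/2,9.39,29.34,0.59,6.3,34.16,FULL,34.70,FULL
1/2,1/2,9.39,29.35,0.29,3.1,35.35,FULL,36.21,FULL
1/4,1/2,9.39,29.33,0.15,1.6,36.15,FULL,37.30,FULL
1/8,1/2,9.39,29.41,0.07,0.8,37.41,PARTIAL,38.07,FULL
1/16,1/2,9.39,29.53,0.04,0.4,39.84,PARTIAL,38.63,FULL
1/32,1/2,9.39,29.38,0.02,0.2,37.95,PARTIAL,38.74,PARTIAL
1/64,1/2,9.39,29.26,0.01,0.1,36.83,PARTIAL,,NONE
1,1/4,4.70,30.73,0.29,6.3,35.28,FULL,36.78,FULL
1/2,1/4,4.70,31.08,0.15,3.1,37.59,FULL,37.73,FULL
1/4,1/4,4.70,31.10,0.07,1.6,39.17,PARTIAL,38.18,PARTIAL
1/8,1/4,4.70,30.64,0.04,0.8,38.12,PARTIAL,37.71,PARTIAL
1/16,1/4,4.70,30.95,0.02,0.4,39.74,PARTIAL,,NONE
1/32,1/4,4.70,30.78,0.01,0.2,,NONE,,NONE
1/64,1/4,4.70,30.83,0.005,0.1,37.96,PARTIAL,,NONE
1,1/8,2.35,31.61,0.15,6.3,36.67,FULL,37.10,FULL
1/2,1/8,2.35,32.04,0.07,3.1,37.45,PARTIAL,38.10,PARTIAL
1/4,1/8,2.35,31.93,0.04,1.6,38.14,PARTIAL,38.48,PARTIAL
1/8,1/8,2.35,31.81,0.02,0.8,37.96,PARTIAL,,NONE
1/16,1/8,2.35,31.92,0.01,0.4,41.02,PARTIAL,38.93,PARTIAL
1/32,1/8,2.35,31.62,0.005,0.2,,NONE,,NONE
1/64,1/8,2.35,31.62,0.002,0.1,,NONE,,NONE
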