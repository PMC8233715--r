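fraction,analyte,n,sec,r2c,sep,r2p,rpd,consistency
phospholipid,12:0,206,0.04,0.48,0.15,0.07,1.06,26.67
phospholipid,14:0,215,0.46,0.77,0.73,0.52,1.44,63.01
phospholipid,16:0,210,7.52,0.67,10.45,0.48,1.43,71.96
phospholipid,16:0ald,210,5.31,0.24,6.70,0.13,1.08,79.25
phospholipid,16:1,205,1.35,0.44,1.85,0.32,1.24,72.97
phospholipid,18:0,211,5.72,0.50,6.92,0.36,1.27,82.66
phospholipid,18:0ald,210,3.10,0.40,5.17,0.10,1.06,59.96
phospholipid,18:1t9,200,1.56,0.19,2.89,0.03,1.01,53.98
phospholipid,18:1c9,205,14.91,0.50,18.81,0.37,1.29,79.27
phospholipid,18:1c11,212,2.66,0.20,3.51,0.09,1.05,75.78
phospholipid,18:2n-6,200,18.81,0.42,33.94,0.04,0.87,55.42
phospholipid,20:1,215,0.15,0.49,0.20,0.27,1.16,75.00
phospholipid,18:3n-3,207,2.26,0.69,3.11,0.53,1.46,72.67
phospholipid,CLA9c11t,200,0.25,0.36,0.43,0.06,1.04,58.14
phospholipid,20:3n-6,201,1.56,0.26,2.08,0.11,1.07,75.00
phospholipid,20:4n-6,201,5.88,0.55,7.59,0.29,1.28,77.47
phospholipid,20:5n-3,202,1.34,0.56,1.74,0.41,1.30,77.01
phospholipid,22:4n-6,207,1.10,0.59,1.58,0.29,1.23,69.62
phospholipid,22:5n-3,200,1.73,0.58,2.47,0.41,1.33,70.04
phospholipid,22:6n-3,198,0.28,0.12,0.38,0.05,1.07,73.68
phospholipid,TotalFA,199,39.14,0.67,63.88,0.44,1.40,61.27
phospholipid,SFA,202,14.80,0.65,20.68,0.57,1.50,71.57
phospholipid,MUFA,210,17.46,0.53,18.85,0.50,1.50,92.63
phospholipid,PUFA,198,19.77,0.65,31.84,0.14,1.24,62.09
total,12:0,222,1.02,0.70,0.97,0.72,1.9,105.15
total,14:0,219,26.05,0.77,27.97,0.74,2.0,93.14
total,16:0,222,233.56,0.71,234.99,0.72,1.9,99.39
total,16:0ald,222,5.98,0.13,6.66,0.16,1.0,89.79
total,16:1,218,32.17,0.76,30.31,0.78,2.1,106.14
total,18:0,222,158.17,0.61,129.39,0.70,1.8,122.24
total,18:0ald,222,3.79,0.53,4.85,0.21,1.1,78.14
total,18:1t9,219,41.01,0.47,50.16,0.47,1.4,81.76
total,18:1c9,217,244.72,0.80,274.92,0.77,2.1,88.59
total,18:1c11,218,12.14,0.77,12.69,0.74,2.0,95.67
total,18:2n-6,222,41.63,0.56,41.32,0.43,1.3,100.75
total,20:1,220,1.40,0.80,1.10,0.71,1.8,127.27
total,18:3n-3,222,7.73,0.60,7.07,0.65,1.7,109.34
total,CLA9c11t,222,4.00,0.61,3.25,0.62,1.6,123.08
total,20:3n-6,217,1.45,0.64,2.09,0.39,1.3,69.38
total,20:4n-6,222,4.89,0.74,8.60,0.26,1.2,56.86
total,20:5n-3,210,1.71,0.39,1.90,0.38,1.3,90.00
total,22:4n-6,217,1.00,0.78,1.74,0.39,1.3,57.47
total,22:5n-3,211,2.47,0.37,2.79,0.36,1.2,88.53
total,22:6n-3,222,0.61,0.01,0.60,0.01,1.0,101.67
total,TotalFA,222,908.22,0.74,730.79,0.79,2.2,124.28
total,SFA,222,412.56,0.73,355.68,0.77,2.1,115.99
total,MUFA,222,393.64,0.77,340.36,0.77,2.1,115.65
total,PUFA,222,53.35,0.54,53.81,0.45,1.3,99.15
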