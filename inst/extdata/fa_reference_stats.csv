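fraction,analyte,set,mean,min,max,sd,cv
phospholipid,12:0,calibration,0.06,0.00,0.53,0.08,133.33
phospholipid,14:0,calibration,1.64,0.34,6.34,1.13,68.90
phospholipid,16:0,calibration,64.42,34.05,109.85,14.34,22.26
phospholipid,16:0ald,calibration,23.42,3.91,43.46,6.42,27.41
phospholipid,16:1,calibration,7.36,3.07,19.35,2.33,31.66
phospholipid,18:0,calibration,52.38,29.16,83.93,8.85,16.90
phospholipid,18:0ald,calibration,15.87,3.47,26.64,4.48,28.23
phospholipid,18:1t9,calibration,4.39,0.93,14.20,2.75,62.64
phospholipid,18:1c9,calibration,76.72,26.06,182.51,24.35,31.74
phospholipid,18:1c11,calibration,14.58,7.87,25.92,3.43,23.53
phospholipid,18:2n-6,calibration,124.47,62.45,210.43,29.61,23.79
phospholipid,20:1,calibration,0.57,0.00,1.20,0.22,38.60
phospholipid,18:3n-3,calibration,6.37,1.51,22.07,4.35,68.29
phospholipid,CLA9c11t,calibration,0.75,0.18,2.49,0.41,54.67
phospholipid,20:3n-6,calibration,8.43,4.94,15.00,2.00,23.72
phospholipid,20:4n-6,calibration,37.84,20.29,69.55,9.39,24.82
phospholipid,20:5n-3,calibration,4.02,1.00,12.07,2.01,50.00
phospholipid,22:4n-6,calibration,4.59,1.34,10.40,1.82,39.65
phospholipid,22:5n-3,calibration,9.17,4.26,21.13,2.94,32.06
phospholipid,22:6n-3,calibration,0.87,0.00,4.85,0.48,55.17
phospholipid,TotalFA,calibration,493.81,270.43,813.78,85.49,17.31
phospholipid,SFA,calibration,157.80,89.26,252.16,28.679,18.17
phospholipid,MUFA,calibration,103.61,46.35,228.31,28.18,27.20
phospholipid,PUFA,calibration,196.51,107.55,319.65,39.61,20.16
phospholipid,12:0,validation,0.09,0.57,1.32,0.16,177.78
phospholipid,14:0,validation,1.62,2.49,4.96,1.05,64.81
phospholipid,16:0,validation,65.92,64.20,103.23,14.93,22.65
phospholipid,16:0ald,validation,24.00,4.650,40.99,7.27,30.29
phospholipid,16:1,validation,7.47,6.17,13.79,2.30,30.79
phospholipid,18:0,validation,53.44,69.77,73.38,8.81,16.49
phospholipid,18:0ald,validation,16.64,3.36,31.87,5.47,32.87
phospholipid,18:1t9,validation,4.47,6.95,16.85,2.91,65.10
phospholipid,18:1c9,validation,77.08,53.77,137.56,24.19,31.38
phospholipid,18:1c11,validation,14.79,11.29,26.03,3.69,24.95
phospholipid,18:2n-6,validation,127.88,67.43,199.28,29.67,23.20
phospholipid,20:1,validation,0.59,0.30,1.26,0.23,38.98
phospholipid,18:3n-3,validation,6.57,3.58,19.57,4.55,69.25
phospholipid,CLA9c11t,validation,0.77,0.70,2.71,0.45,58.44
phospholipid,20:3n-6,validation,8.44,3.60,13.66,2.22,26.30
phospholipid,20:4n-6,validation,38.63,16.27,69.77,9.69,25.08
phospholipid,20:5n-3,validation,4.20,1.23,10.97,2.27,54.05
phospholipid,22:4n-6,validation,4.67,1.10,10.21,1.94,41.54
phospholipid,22:5n-3,validation,9.35,3.43,20.38,3.30,35.29
phospholipid,22:6n-3,validation,0.85,0.00,2.28,0.40,47.06
phospholipid,TotalFA,validation,504.13,467.25,726.78,89.74,17.80
phospholipid,SFA,validation,161.71,101.33,228.035,31.09,19.23
phospholipid,MUFA,validation,104.400,47.82,169.93,28.26,27.07
phospholipid,PUFA,validation,201.36,103.90,297.84,40.64,20.18
total,12:0,calibration,2.10,0.00,8.86,1.87,89.05
total,14:0,calibration,73.63,0.87,313.13,58.97,80.09
total,16:0,calibration,651.20,51.20,2878.25,480.58,73.80
total,16:0ald,calibration,23.42,3.91,43.46,6.42,27.41
total,16:1,calibration,92.50,5.55,414.79,73.77,79.75
total,18:0,calibration,401.08,50.04,1741.09,254.19,63.38
total,18:0ald,calibration,15.87,3.47,26.64,4.48,28.23
total,18:1t9,calibration,77.48,3.47,625.86,76.14,98.27
total,18:1c9,calibration,854.17,31.86,4125.90,658.56,77.10
total,18:1c11,calibration,49.02,11.24,191.83,29.18,59.53
total,18:2n-6,calibration,183.30,83.15,500.18,62.86,34.29
total,20:1,calibration,4.03,0.27,22.16,3.28,81.39
total,18:3n-3,calibration,15.16,2.70,69.20,12.27,80.94
total,CLA9c11t,calibration,8.14,0.45,43.18,6.39,78.50
total,20:3n-6,calibration,9.14,5.15,16.12,2.48,27.13
total,20:4n-6,calibration,38.56,20.29,71.23,9.60,24.90
total,20:5n-3,calibration,4.18,1.00,15.56,2.18,52.15
total,22:4n-6,calibration,4.91,1.34,11.33,2.15,43.79
total,22:5n-3,calibration,9.61,4.26,21.85,3.11,32.36
total,22:6n-3,calibration,0.91,0.00,4.95,0.61,67.03
total,TotalFA,calibration,2701.26,452.75,10922.01,1780.47,65.91
total,SFA,calibration,1167.30,133.90,4981.92,790.24,67.70
total,MUFA,calibration,1077.19,54.47,4916.56,818.18,75.96
total,PUFA,calibration,265.76,139.73,607.29,79.13,29.77
total,12:0,validation,2.06,0.06,8.69,1.80,87.38
total,14:0,validation,71.57,2.49,256.53,55.15,77.06
total,16:0,validation,639.85,64.20,2420.91,442.30,69.13
total,16:0ald,validation,24.00,4.65,40.99,7.27,30.29
total,16:1,validation,89.04,6.17,266.67,64.18,72.08
total,18:0,validation,398.22,69.77,1497.58,237.68,59.69
total,18:0ald,validation,16.64,3.36,31.87,5.47,32.87
total,18:1t9,validation,75.20,6.95,363.93,68.72,91.38
total,18:1c9,validation,831.04,53.77,2866.55,573.11,68.96
total,18:1c11,validation,47.77,11.29,119.64,25.02,52.38
total,18:2n-6,validation,183.30,67.43,314.36,54.76,29.87
total,20:1,validation,3.77,0.30,13.58,2.58,68.44
total,18:3n-3,validation,14.99,3.58,48.81,11.81,78.79
total,CLA9c11t,validation,7.84,0.70,27.41,5.26,67.09
total,20:3n-6,validation,9.11,3.60,16.29,2.67,29.31
total,20:4n-6,validation,39.32,16.27,70.47,10.01,25.46
total,20:5n-3,validation,4.35,1.23,11.41,2.37,54.48
total,22:4n-6,validation,4.96,1.10,11.70,2.26,45.56
total,22:5n-3,validation,9.82,3.43,20.65,3.47,35.34
total,22:6n-3,validation,0.89,0.00,5.56,0.60,67.42
total,TotalFA,validation,2652.12,467.25,8701.06,1596.84,60.21
total,SFA,validation,1152.34,157.41,4182.02,734.39,63.73
total,MUFA,validation,1046.83,78.48,3570.11,713.46,68.15
total,PUFA,validation,266.73,114.32,439.52,72.54,27.20
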