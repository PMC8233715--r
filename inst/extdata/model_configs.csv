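fraction,analyte,baseline,normalization,scatter,smooth,math,factors
phospholipid,12:0,Offset,None,EMSC,None,None,6
phospholipid,14:0,Offset,None,EMSC,None,SG-1-2-5,5
phospholipid,16:0,Offset,Area,SNV+D,None,SG-1-2-3,4
phospholipid,16:0ald,None,None,None,None,SG-1-2-3,3
phospholipid,16:1,Offset,None,None,None,None,4
phospholipid,18:0,Offset,Area,EMSC,None,None,4
phospholipid,18:0ald,Offset,Area,SNV+D,None,None,6
phospholipid,18:1t9,None,None,EMSC,None,None,3
phospholipid,18:1c9,None,None,None,None,SG-1-2-5,2
phospholipid,18:1c11,Offset,Area,SNV+D,None,None,3
phospholipid,18:2n-6,None,None,None,None,None,8
phospholipid,20:1,Offset,Area,SNV,None,None,6
phospholipid,18:3n-3,Offset,None,None,None,None,10
phospholipid,CLA9c11t,Offset,Area,SNV+D,None,None,5
phospholipid,20:3n-6,None,None,EMSC,None,None,3
phospholipid,20:4n-6,None,Area,SNV,None,None,12
phospholipid,20:5n-3,Offset,Area,EMSC+D,None,None,8
phospholipid,22:4n-6,None,None,None,None,SG-1-2-3,5
phospholipid,22:5n-3,Offset,Area,None,None,None,10
phospholipid,22:6n-3,None,Area,None,None,None,1
phospholipid,TotalFA,Offset,Area,None,None,SG-1-2-5,5
phospholipid,SFA,Offset,None,SNV,None,None,6
phospholipid,MUFA,None,None,SNV,None,None,5
phospholipid,PUFA,Offset,Area,None,None,SG-1-2-3,5
total,12:0,None,None,SNV+D,None,SG-1-2-3,4
total,14:0,None,Area,SNV+D,None,SG-1-2-3,3
total,16:0,None,Area,SNV+D,None,SG-1-2-3,3
total,16:0ald,None,None,None,None,None,2
total,16:1,None,None,None,SG1-1-1,None,8
total,18:0,None,None,None,None,None,5
total,18:0ald,None,None,SNV+D,None,None,8
total,18:1t9,None,None,SNV+D,None,None,2
total,18:1c9,None,None,None,None,NG-1-13,7
total,18:1c11,None,Area,SNV+D,None,None,11
total,18:2n-6,None,None,None,SG1-2-2,SG-1-2-3,5
total,20:1,None,None,None,None,SG-1-2-3,4
total,18:3n-3,Offset,None,None,None,None,9
total,CLA9c11t,None,None,MSC,None,SG-1-2-3,4
total,20:3n-6,None,None,None,None,NG-1-7,7
total,20:4n-6,None,None,None,None,SG-1-2-3,7
total,20:5n-3,None,None,None,None,NG-1-15,7
total,22:4n-6,None,None,None,None,SG-1-2-3,6
total,22:5n-3,None,None,SNV,None,NG-1-7,5
total,22:6n-3,None,None,None,None,None,1
total,TotalFA,Offset,None,None,None,None,9
total,SFA,None,None,None,None,None,9
total,MUFA,None,None,None,None,NG-1-27,7
total,PUFA,None,None,None,None,NG-1-11,6
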