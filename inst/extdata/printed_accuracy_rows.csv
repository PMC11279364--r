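target,measure,criterion,stratum,marker,n_pos,n_neg,se_pct,sp_pct
t1,yi,ATP_III,male 20-39,METS_IR,506,1216,88.5,71.3
t2,lrp,ATP_III,male 20-39,METS_IR,506,1216,88.5,71.3
t3,lrn,ATP_III,male 20-39,METS_IR,506,1216,88.5,71.3
t4,ppv,ATP_III,male 20-39,METS_IR,506,1216,88.5,71.3
t5,npv,ATP_III,male 20-39,METS_IR,506,1216,88.5,71.3
t6,yi,ATP_III,male 60+,LAP,536,569,87.6,73.2
t7,yi,ATP_III,female 20-39,LAP,825,1459,92.4,78.1
t8,yi,IDF,female 20-39,TYG,1017,1267,89.8,73.3
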