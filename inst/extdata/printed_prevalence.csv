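target,label,count,total
t9,mets_atp3_men,1808,4534
t10,mets_idf_women,3624,6041
,aged_40_59,4095,10575
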