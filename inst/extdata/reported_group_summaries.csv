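metric,unit,group,mean,sem,n
total_delivery,ul/min,WKY,14.4,1.92,6
total_delivery,ul/min,SHR,9.22,1.20,6
cbf,ml/min/100g,WKY,123,7.4,6
cbf,ml/min/100g,SHR,118,8.7,6
t1_csf,s,WKY,4.24,0.04,6
t1_csf,s,SHR,4.58,0.06,6
t1_cortex,s,WKY,1.88,0.01,6
t1_cortex,s,SHR,1.91,0.01,6
ventricular_volume,mm3,WKY,56,3.0,6
ventricular_volume,mm3,SHR,83,1.0,6
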