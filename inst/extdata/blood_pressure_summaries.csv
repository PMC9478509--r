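metric,unit,group,mean,sem,n
systolic,mmHg,WKY,105,12,4
systolic,mmHg,SHR,185,6.5,4
diastolic,mmHg,WKY,55,7.4,4
diastolic,mmHg,SHR,113,7.5,4
mean_pressure,mmHg,WKY,80,9.5,4
mean_pressure,mmHg,SHR,149,6.9,4
pulse_pressure,mmHg,WKY,50,5.4,4
pulse_pressure,mmHg,SHR,73,2.5,4
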