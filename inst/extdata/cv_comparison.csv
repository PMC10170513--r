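compound,cv_set,log_tau,sem,log_rt
tiotropium,3cv,22.8,1.03,3.44
tiotropium,4cv_a,19.2,1.02,3.44
tiotropium,4cv_b,16.9,0.72,3.44
tiotropium,5cv,14.6,0.63,3.44
9,3cv,18.6,1.21,1.69
9,4cv_a,14.5,0.85,1.69
9,4cv_b,13.0,0.62,1.69
9,5cv,9.80,0.53,1.69
1,3cv,10.7,1.36,0.59
1,4cv_a,10.1,0.85,0.59
1,4cv_b,8.02,0.49,0.59
1,5cv,6.79,0.67,0.59
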