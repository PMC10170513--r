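compound,log_rt,log_tau,sem,similarity,congeneric,log_rt_pred,residual
tiotropium,3.44,14.6,0.63,1.00,TRUE,3.21,0.23
6,2.84,13.5,0.64,0.62,TRUE,2.83,0.01
8,2.82,13.6,0.69,0.69,TRUE,2.86,-0.04
5,2.10,12.3,0.87,0.63,TRUE,2.41,-0.31
3,1.96,10.7,1.18,0.63,TRUE,1.85,0.11
9,1.69,9.80,0.53,0.59,TRUE,1.54,0.15
7,1.29,9.74,0.75,0.61,TRUE,1.52,-0.23
1,0.59,6.79,0.67,0.62,TRUE,0.49,0.10
NMS,2.16,7.70,0.61,0.41,FALSE,0.81,1.35
ipratropium,1.39,8.53,1.17,0.17,FALSE,1.10,0.29
10,1.10,10.9,1.10,0.48,FALSE,1.92,-0.82
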