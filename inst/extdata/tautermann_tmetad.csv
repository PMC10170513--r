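compound,log_rt,t_metad,sem,similarity,congeneric,log_rt_pred,residual
tiotropium,3.44,25.9,2.19,1.00,TRUE,2.86,0.58
6,2.84,26.2,1.50,0.62,TRUE,2.91,-0.07
8,2.82,23.8,1.53,0.69,TRUE,2.52,0.30
5,2.10,20.0,1.27,0.63,TRUE,1.89,0.21
3,1.96,24.0,1.98,0.63,TRUE,2.55,-0.59
9,1.69,22.2,2.02,0.59,TRUE,2.25,-0.56
7,1.29,15.0,0.95,0.61,TRUE,1.07,0.22
1,0.59,12.6,0.70,0.62,TRUE,0.67,-0.08
NMS,2.16,17.0,1.42,0.41,FALSE,1.40,0.76
ipratropium,1.39,12.0,0.71,0.17,FALSE,0.57,0.82
10,1.10,16.9,1.05,0.48,FALSE,1.38,-0.28
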