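compound,log_rt,log_tau,sem,similarity,congeneric,log_rt_pred,residual
tiotropium,3.27,14.6,0.63,1.00,TRUE,3.31,-0.04
BS46,3.11,13.0,1.11,0.22,TRUE,2.98,0.13
darifenacin,2.31,10.4,0.58,0.10,TRUE,2.45,-0.14
NMS,1.96,7.70,0.61,0.41,TRUE,1.90,0.06
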