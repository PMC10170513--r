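compound,log_rt,t_metad,sem,similarity,congeneric,log_rt_pred,residual
tiotropium,3.27,25.9,2.19,1.00,TRUE,3.38,-0.11
BS46,3.11,23.1,1.12,0.22,TRUE,2.96,0.15
darifenacin,2.31,18.7,1.68,0.10,TRUE,2.29,0.02
NMS,1.96,17.0,1.42,0.41,TRUE,2.03,-0.07
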