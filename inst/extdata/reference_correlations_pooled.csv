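group,input_variable,output_variable,r,p_value,intercept,slope
POOLED,L-MPH,moisture,0.37,0.01,68.61,0.22
POOLED,T-MPI,L_24h,0.29,0.05,54.49,0.07
POOLED,T-MPI,thermal_loss,-0.30,0.04,31.39,-0.09
POOLED,O1-MPI,aroma_desirability,-0.30,0.05,4.70,-0.005
POOLED,O1-MPI,C_24h,-0.34,0.02,10.52,-0.06
POOLED,O1-MPH,cohesiveness,-0.36,0.02,5.01,-0.02
POOLED,O1-MPH,aroma_intensity,-0.41,0.005,5.00,-0.03
POOLED,O2-MPI,L_0h,0.30,0.05,49.39,0.14
POOLED,O2-MPI,C_24h,-0.30,0.05,10.62,-0.05
POOLED,O2-MPH,C_24h,-0.31,0.04,11.66,-0.17
POOLED,O2-MPH,L_0h,0.33,0.03,45.74,0.54
POOLED,O2-MPH,aroma_intensity,-0.31,0.04,4.85,-0.02
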