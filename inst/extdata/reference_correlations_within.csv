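group,input_variable,output_variable,r,p_value,intercept,slope
C,L-MPI,L_0h,0.54,0.04,54.69,0.13
C,T-MPI,thermal_loss,-0.67,0.006,34.54,-0.15
C,T-MPH,cutting_force,0.59,0.03,5.45,0.73
C,O1-MPI,C_24h,0.59,0.02,5.60,0.02
C,O1-MPI,protein,-0.57,0.03,27.67,-0.07
C,O1-MPI,flavor_intensity,0.51,0.05,4.14,0.007
C,O1-MPH,thermal_loss,-0.57,0.02,42.60,-0.77
C,O1-MPH,h_24h,0.54,0.04,-4.98,0.21
C,O1-MPH,moisture,0.51,0.05,71.00,0.11
C,O2-MPI,cutting_force,0.66,0.07,6.86,0.20
Exp1,L-MPI,b_0h,-0.57,0.03,0.91,-0.04
Exp2,L-MPI,hardness,-0.55,0.03,0.56,-0.002
Exp2,L-MPI,L_0h,-0.51,0.05,68.96,-0.27
Exp2,L-MPH,moisture,0.67,0.006,66.24,0.42
Exp2,T-MPI,cutting_force,0.58,0.02,0.53,0.05
Exp2,O1-MPI,L_0h,-0.57,0.03,68.34,-0.35
Exp2,O1-MPI,a_0h,0.63,0.01,3.20,0.14
Exp2,O2-MPI,flavor_desirability,0.57,0.03,3.98,0.01
Exp2,O2-MPH,cohesiveness,-0.53,0.04,5.24,-0.03
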