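variable,type,mean_C,sem_C,mean_Exp1,sem_Exp1,mean_Exp2,sem_Exp2
body_weight,morphometric,10.7,0.06,10.3,0.07,9.8,0.06
carcass_weight,morphometric,8.8,0.04,8.1,0.06,7.8,0.04
muscle_weight,morphometric,1369,22,1239,20,1114,13
moisture,chemical,73.1,0.1,72.1,0.2,74.2,0.3
protein,chemical,24.35,0.29,24.30,0.31,23.86,0.16
crude_fat,chemical,2.03,0.22,1.19,0.16,1.79,0.23
fiber_diameter,morphometric,75.5,2.0,72.4,1.7,68.9,0.9
pH_0h,physical,6.48,0.05,6.07,0.06,6.06,0.07
L_0h,physical,61.6,0.4,53.0,0.9,56.0,1.0
a_0h,physical,6.5,0.08,9.2,0.4,8.1,0.4
b_0h,physical,-1.5,0.2,-1.1,0.2,-1.8,0.3
pH_24h,physical,5.61,0.02,5.61,0.02,5.65,0.03
L_24h,physical,57.6,0.5,57.1,0.6,56.8,0.7
a_24h,physical,10.2,0.2,10.3,0.2,10.9,0.4
b_24h,physical,1.6,0.4,1.5,0.2,1.2,0.3
C_24h,physical,6.8,0.1,9.3,0.4,8.4,0.3
h_24h,physical,-1.14,0.19,-1.23,0.20,-1.14,0.19
hardness,physical,100.8,0.9,110.9,10.2,118.0,11.7
springiness,physical,0.50,0.02,0.57,0.02,0.52,0.01
chewiness,physical,22.2,2.4,28.3,3.3,27.8,3.2
cutting_force,physical,18.0,0.8,20.1,3.5,23.7,1.6
thermal_loss,physical,28.4,0.7,26.6,0.7,28.3,0.8
tenderness,sensory,4.44,0.03,4.50,0.04,4.53,0.04
cohesiveness,sensory,4.46,0.04,4.65,0.003,4.64,0.03
juiciness,sensory,4.36,0.04,4.51,0.04,4.55,0.04
aroma_intensity,sensory,4.40,0.04,4.55,0.02,4.61,0.03
aroma_desirability,sensory,4.38,0.03,4.53,0.03,4.60,0.03
flavor_intensity,sensory,4.49,0.03,4.48,0.03,4.57,0.03
flavor_desirability,sensory,4.40,0.02,4.48,0.04,4.60,0.03
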