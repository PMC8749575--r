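variable,mean_C,sem_C,mean_Exp1,sem_Exp1,mean_Exp2,sem_Exp2
L-MPI,52.6,1.9,47.9,2.6,48.3,1.9
T-MPI,42.0,3.0,38.8,2.1,36.4,1.8
O1-MPI,47.6,2.4,38.7,1.8,35.5,1.6
O2-MPI,56.6,2.8,49.5,2.6,48.3,1.5
L-MPH,19.3,0.5,17.5,0.4,18.7,0.5
T-MPH,17.1,0.6,17.5,0.5,17.6,0.6
O1-MPH,18.5,0.5,17.3,0.5,16.1,0.6
O2-MPH,21.5,0.8,19.3,0.7,20.3,0.6
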