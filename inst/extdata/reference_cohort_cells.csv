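metric,timepoint,segment,configuration,median,iqr
diameter,PRE,SFA,straight,7.93,3.5
diameter,PRE,SFA,bent,9,3.86
diameter,PRE,PA,straight,9.06,3.82
diameter,PRE,PA,bent,9,4.7
diameter,FU1,SFA,straight,7.59,3.17
diameter,FU1,SFA,bent,8.52,4.4
diameter,FU1,PA,straight,6.8,3.87
diameter,FU1,PA,bent,6.5,3.81
length,PRE,SFA,straight,291.14,47.81
length,PRE,SFA,bent,280.95,46.97
length,PRE,PA,straight,218.31,42
length,PRE,PA,bent,207.83,36.28
length,FU1,SFA,straight,291.03,45.1
length,FU1,SFA,bent,287.5,45.1
length,FU1,PA,straight,208.17,34.1
length,FU1,PA,bent,196.45,39.98
tortuosity,PRE,SFA,straight,0.027,0.01
tortuosity,PRE,SFA,bent,0.05,0.025
tortuosity,PRE,PA,straight,0.083,0.059
tortuosity,PRE,PA,bent,0.19,0.12
tortuosity,FU1,SFA,straight,0.03,0.011
tortuosity,FU1,SFA,bent,0.06,0.04
tortuosity,FU1,PA,straight,0.062,0.043
tortuosity,FU1,PA,bent,0.22,0.07
t_front,PRE,PA,straight,0.026,0.036
t_front,PRE,PA,bent,0.14,0.12
t_lat,PRE,PA,straight,0.05,0.027
t_lat,PRE,PA,bent,0.087,0.052
t_front,FU1,PA,straight,0.025,0.03
t_front,FU1,PA,bent,0.15,0.1
t_lat,FU1,PA,straight,0.043,0.022
t_lat,FU1,PA,bent,0.093,0.04
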