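variable,group,mean,sd,n,range_lo,range_hi
age,all,60,13,24,27,76
age,no_ph,59,8,6,50,71
age,ph,61,15,18,27,76
BSA,all,2.0,0.3,24,1.6,2.9
BSA,no_ph,2.0,0.2,6,1.8,2.3
BSA,ph,2.0,0.3,18,1.6,2.9
mPAP,all,36,15,24,14,66
mPAP,no_ph,17,2,6,14,20
mPAP,ph,43,12,18,26,66
PAWP,all,9,3,24,3,15
PAWP,no_ph,8,2,6,5,11
PAWP,ph,9,3,18,3,15
CO,all,4.5,1.2,24,2.9,7.8
CO,no_ph,5.5,1.5,6,4.3,7.8
CO,ph,4.2,0.9,18,2.9,5.7
PVR,all,540,370,24,80,1420
PVR,no_ph,110,20,6,80,130
PVR,ph,680,320,18,230,1420
AVDO2,all,4.9,1.0,24,2.4,6.4
AVDO2,no_ph,4.0,0.5,6,3.3,4.7
AVDO2,ph,5.2,1.0,18,2.4,6.4
artSO2,all,94,2,24,89,98
artSO2,no_ph,96,1,6,95,98
artSO2,ph,93,2,18,89,98
venSO2,all,68,7,24,50,84
venSO2,no_ph,74,2,6,71,76
venSO2,ph,66,7,18,50,84
distance_metric,all,1.224,0.019,24,1.199,1.273
distance_metric,no_ph,1.208,0.009,6,1.199,1.223
distance_metric,ph,1.230,0.019,18,1.202,1.273
fractal_dimension,all,2.35,0.06,24,2.21,2.44
fractal_dimension,no_ph,2.37,0.08,6,2.21,2.43
fractal_dimension,ph,2.34,0.05,18,2.27,2.44
n_segments,all,12427,3508,24,5922,20434
n_segments,no_ph,11719,3041,6,5922,14642
n_segments,ph,12392,3616,18,7815,20434
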