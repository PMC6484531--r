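quantity,plate,well,parameter,bin,value
edge,P1,NA,u_uniform,1,2.0800000000000011e+01
edge,P1,NA,u_uniform,2,4.0600000000000023e+01
edge,P1,NA,u_uniform,3,6.0399999999999977e+01
edge,P1,NA,u_uniform,4,8.0200000000000045e+01
edge,P1,NA,g_drift,1,-7.0306624681454399e-01
edge,P1,NA,g_drift,2,-8.5144807571300718e-02
edge,P1,NA,g_drift,3,4.5858475428777545e-01
edge,P1,NA,g_drift,4,1.0977109536659602e+00
count,P1,D6,g_drift,1,4.0000000000000000e+00
count,P1,D6,g_drift,2,9.0000000000000000e+00
count,P1,D6,g_drift,3,1.4000000000000000e+01
count,P1,D6,g_drift,4,2.5000000000000000e+01
count,P1,D6,g_drift,5,4.8000000000000000e+01
chi2,P1,D6,g_drift,NA,6.1100000000000001e+01
p,P1,D6,g_drift,NA,1.7033462606063351e-12
count,P1,T2,g_bimodal,1,4.3000000000000000e+01
count,P1,T2,g_bimodal,2,6.0000000000000000e+00
count,P1,T2,g_bimodal,3,2.0000000000000000e+00
count,P1,T2,g_bimodal,4,5.0000000000000000e+00
count,P1,T2,g_bimodal,5,4.4000000000000000e+01
z,P1,T2,g_bimodal,1,3.6366193091936360e+01
z,P1,T2,g_bimodal,5,3.7947331922020552e+01
fraction_passing,NA,NA,g_drift,NA,8.3333333333333337e-01
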