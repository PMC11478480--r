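condition,own_rmse,own_r2,cross_rmse,cross_r2,rrmse_pct,apee_pct,nrmse_pct
LW,0.658,0.922,1.845,0.780,1.31,0.66,0.66
SA,0.939,0.889,3.365,0.612,1.87,0.94,0.94
SD,0.917,0.892,2.842,0.723,1.80,0.93,0.92
RA,0.682,0.920,2.144,0.758,1.37,1.06,0.68
RD,0.775,0.908,1.974,0.767,1.55,0.78,0.78
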