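trait,split,n_obs,n_val,transformation,n_comp,rmse,range,pct_rmse,r2,pct_rmse_consistent
vcmax25,random,302,59,sqrt,18,13.1,149.3,8.8,0.74,TRUE
vcmax25,species,302,34,sqrt,18,11.2,149.3,7.5,0.86,TRUE
vcmax25,site,302,43,sqrt,18,8.2,149.3,5.5,0.66,TRUE
jmax25,random,286,56,sqrt,18,19.8,237.3,8.4,0.73,FALSE
jmax25,species,286,34,sqrt,18,17.6,237.3,7.4,0.86,TRUE
jmax25,site,286,30,sqrt,18,16.6,237.3,7.0,0.38,TRUE
tp25,random,99,18,none,3,1.52,12.3,12.4,0.64,TRUE
tp25,species,99,19,none,3,1.44,12.3,11.7,0.74,TRUE
rdark25,random,168,49,none,11,0.27,2.8,9.5,0.58,FALSE
rdark25,species,168,12,none,11,0.23,2.8,8.4,0.50,FALSE
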