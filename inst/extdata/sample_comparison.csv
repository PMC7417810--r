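label,section,method,mean_prev,sd_prev,n_prev,mean_cur,sd_cur,n_cur,count_prev,count_cur,printed_stat,printed_p,reproducible
age,baseline,pooled,37.9,13.36,16636,37.56,14.36,44095,NA,NA,2.651,0.008,TRUE
phq9,baseline,pooled,13.85,6.67,16636,13.8,6.46,44095,NA,NA,0.843,0.399,TRUE
gad7,baseline,pooled,12.35,5.51,16636,12.35,5.43,44095,NA,NA,0,1,TRUE
wsas,baseline,pooled,17.85,9.69,16636,17.17,9.2,44095,NA,NA,8.004,0.001,TRUE
female,baseline,z,NA,NA,16636,NA,NA,44095,10793,29561,2.82,0.005,FALSE
nonwhite,baseline,z,NA,NA,16636,NA,NA,44095,3151,11242,18.34,0.001,FALSE
medication,baseline,z,NA,NA,16636,NA,NA,44095,5802,21310,26.84,0.001,FALSE
welfare,baseline,z,NA,NA,16636,NA,NA,44095,3834,11230,-5.36,0.001,FALSE
phobia,baseline,z,NA,NA,16636,NA,NA,44095,7592,20992,3.22,0.001,FALSE
sessions,endpoint,welch,6.87,5.68,10693,9.35,5.86,18514,NA,NA,-35.53,0.001,TRUE
phq9_end,endpoint,welch,10.44,6.92,10693,9.52,6.4,18514,NA,NA,11.25,0.001,TRUE
gad7_end,endpoint,welch,9.23,5.91,10693,8.63,5.6,18514,NA,NA,8.52,0.001,TRUE
wsas_end,endpoint,welch,14.62,10.2,10693,13.27,9.05,18514,NA,NA,10.27,0.001,FALSE
recovered,endpoint,z,NA,NA,10693,NA,NA,18514,4283,8432,-9.12,0.001,TRUE
reliably_improved,endpoint,z,NA,NA,10693,NA,NA,18514,7041,12053,1.29,0.197,TRUE
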