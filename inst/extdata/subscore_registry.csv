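subscore,input,constituent,domain,direction,efwm_facet,ref_mean,age_slope,sex_slope,edu_slope,sd,trial_sd,practice,retest_r
sdmt,TRUE,TRUE,ips,higher,,55,-0.35,-1,1.8,9,,2,0.8
srt_lts,TRUE,TRUE,memory,higher,,45,-0.3,-3,1.5,10,,2,0.75
srt_ltr,TRUE,TRUE,memory,higher,,40,-0.3,-3,1.5,11,,2,0.75
srt_cltr,TRUE,TRUE,memory,higher,,35,-0.35,-3,1.8,12,,2,0.72
srt_delayed,TRUE,TRUE,memory,higher,,7.5,-0.04,-0.5,0.2,2.2,,0.3,0.7
spart_t1,TRUE,FALSE,,higher,,,,,,,,,
spart_t2,TRUE,FALSE,,higher,,,,,,,,,
spart_t3,TRUE,FALSE,,higher,,,,,,,,,
spart_delayed,TRUE,TRUE,memory,higher,,6.8,-0.05,-0.2,0.25,1.9,,0.4,0.7
wlg_animals,TRUE,FALSE,,higher,,,,,,,,,
wlg_professions,TRUE,FALSE,,higher,,,,,,,,,
wlg_m,TRUE,FALSE,,higher,,,,,,,,,
stroop_card1,TRUE,TRUE,attention,lower,,44,0.15,0.5,-1,7,,-1,0.75
stroop_card2,TRUE,TRUE,attention,lower,,56,0.2,0.5,-1.2,9,,-1.5,0.75
stroop_card3,TRUE,FALSE,,lower,,,,,,,,,
cst_numbers,TRUE,TRUE,attention,lower,,32,0.2,0.3,-0.8,6,,-1,0.72
cst_letters,TRUE,TRUE,attention,lower,,33,0.2,0.3,-0.8,6.5,,-1,0.72
cst_shifting,TRUE,TRUE,efwm,lower,flexibility,45,0.3,0.5,-1.2,11,,-2,0.7
mct_1letter,TRUE,FALSE,,lower,,9,0.03,0.1,-0.1,1.5,,-0.2,0.7
mct_4letter,TRUE,FALSE,,lower,,,,,,,,,
spart_direct,FALSE,TRUE,memory,higher,,6.5,-0.05,-0.2,0.25,1.6,1,0.4,0.7
wlg_total,FALSE,TRUE,efwm,higher,fluency,60,-0.25,-2,2.5,12,4,2,0.75
stroop_interference,FALSE,TRUE,efwm,lower,inhibition,35,0.35,1,-2,12,,-2,0.7
mct_slope,FALSE,TRUE,efwm,lower,working_memory,5,0.04,0.1,-0.15,2,,-0.4,0.65
srt_average,FALSE,FALSE,,higher,,,,,,,,,
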