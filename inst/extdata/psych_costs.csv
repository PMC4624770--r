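id,label,delivery,sessions,session_minutes,extra_session_minutes,therapists,participants,contact_minutes,consumable_cost,therapist_unit_cost,p_full,band2_lo,band2_hi,p_band2,band3_lo,band3_hi,p_band3,printed_total
shns_book,"SHNS, book",selfhelp,NA,NA,NA,1,1,75,20.66,110,NA,NA,NA,NA,NA,NA,NA,205
shns_internet,"SHNS, internet",selfhelp,NA,NA,NA,1,1,75,479.67,110,NA,NA,NA,NA,NA,NA,NA,664
shws_book,"SHWS, book",selfhelp,NA,NA,NA,1,1,210,20.66,110,NA,NA,NA,NA,NA,NA,NA,453
shws_internet,"SHWS, internet",selfhelp,NA,NA,NA,1,1,210,479.67,110,NA,NA,NA,NA,NA,NA,NA,912
exposure,Exposure in vivo,group,12,150,0,2,6,NA,0,110,NA,NA,NA,NA,NA,NA,NA,1148
mindfulness,Mindfulness training,group,8,150,450,2,12,NA,0,110,NA,NA,NA,NA,NA,NA,NA,551
gcbt_heimberg,"GCBT, Heimberg",group,12,150,0,2,6,NA,0,110,NA,NA,NA,NA,NA,NA,NA,1148
gcbt_general,"GCBT, general",group,15,120,0,2,6,NA,0,110,NA,NA,NA,NA,NA,NA,NA,1148
ipt,Interpersonal psychotherapy,individual,18,50,0,1,1,NA,0,110,0.70,14,17,0.15,1,13,0.15,1698
pdpt,Psychodynamic psychotherapy,individual,25,50,0,1,1,NA,0,110,0.70,21,24,0.15,1,20,0.15,2341
supportive,Supportive therapy,individual,14,60,0,1,1,NA,0,110,0.70,10,13,0.15,1,9,0.15,1588
icbt_hope,"ICBT, Hope",individual,16,60,30,1,1,NA,0,110,0.70,12,15,0.15,1,11,0.15,1864
icbt_cw,"ICBT, C&W",individual,14,90,0,1,1,NA,0,110,0.80,10,13,0.20,NA,NA,NA,2359
icbt_short,"ICBT, short",individual,14,75,0,1,1,NA,0,110,0.70,10,13,0.15,1,9,0.15,1974
icbt_general,"ICBT, general",individual,16,60,0,1,1,NA,0,110,0.70,12,15,0.15,1,11,0.15,1809
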