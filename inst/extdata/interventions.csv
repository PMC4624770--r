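id,label,class,relapse_class
icbt_cw,"ICBT, C&W",individual-psychological,psychological
phenelzine,Phenelzine,pharmacological,drug
icbt_general,"ICBT, general",individual-psychological,psychological
icbt_hope,"ICBT, Hope",individual-psychological,psychological
paroxetine,Paroxetine,pharmacological,drug
icbt_short,"ICBT, short",individual-psychological,psychological
venlafaxine,Venlafaxine,pharmacological,drug
fluvoxamine,Fluvoxamine,pharmacological,drug
sertraline,Sertraline,pharmacological,drug
escitalopram,Escitalopram,pharmacological,drug
shws_internet,"SHWS, internet",self-help,psychological
fluoxetine,Fluoxetine,pharmacological,drug
shws_book,"SHWS, book",self-help,psychological
gcbt_general,"GCBT, general",group-psychological,psychological
shns_book,"SHNS, book",self-help,psychological
citalopram,Citalopram,pharmacological,drug
exposure,Exposure in vivo,group-psychological,psychological
mirtazapine,Mirtazapine,pharmacological,drug
gcbt_heimberg,"GCBT, Heimberg",group-psychological,psychological
moclobemide,Moclobemide,pharmacological,drug
pregabalin,Pregabalin,pharmacological,drug
shns_internet,"SHNS, internet",self-help,psychological
pdpt,Psychodynamic psychotherapy,individual-psychological,psychological
pill_placebo,Pill placebo,pill-placebo,drug
ipt,Interpersonal psychotherapy,individual-psychological,psychological
mindfulness,Mindfulness training,group-psychological,psychological
supportive,Supportive therapy,individual-psychological,psychological
wait_list,Wait list,wait-list,waitlist
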