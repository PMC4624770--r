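id,label,daily_dose,acq_cost_12wk,acq_cost_26wk,is_placebo,printed_total
citalopram,Citalopram,40 mg,3.84,8.32,FALSE,339.43
escitalopram,Escitalopram,20 mg,6.21,13.46,FALSE,346.93
fluoxetine,Fluoxetine,40 mg,6.50,14.07,FALSE,347.84
fluvoxamine,Fluvoxamine,150 mg,71.48,154.88,FALSE,553.64
mirtazapine,Mirtazapine,30 mg,4.80,10.40,FALSE,342.47
moclobemide,Moclobemide,600 mg,78.34,169.75,FALSE,575.36
paroxetine,Paroxetine,40 mg,12.82,27.79,FALSE,367.88
phenelzine,Phenelzine,60 mg,75.60,163.80,FALSE,566.67
pregabalin,Pregabalin,450 mg,193.20,418.60,FALSE,939.07
sertraline,Sertraline,200 mg,9.96,21.58,FALSE,358.81
venlafaxine,Venlafaxine,150 mg,52.36,113.45,FALSE,493.08
pill_placebo,Pill placebo,NA,0,0,TRUE,327.27
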