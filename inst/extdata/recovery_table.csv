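id,mean,median,ci_low,ci_high
icbt_cw,0.62,0.65,0.16,0.95
phenelzine,0.51,0.51,0.09,0.91
icbt_general,0.47,0.46,0.08,0.90
icbt_hope,0.41,0.38,0.06,0.86
paroxetine,0.40,0.37,0.06,0.85
icbt_short,0.39,0.36,0.05,0.84
venlafaxine,0.38,0.35,0.05,0.84
fluvoxamine,0.37,0.34,0.05,0.84
sertraline,0.37,0.33,0.04,0.83
escitalopram,0.35,0.31,0.04,0.82
shws_internet,0.35,0.31,0.05,0.80
fluoxetine,0.35,0.31,0.04,0.81
shws_book,0.34,0.30,0.04,0.81
gcbt_general,0.34,0.30,0.04,0.80
shns_book,0.34,0.30,0.04,0.80
citalopram,0.34,0.29,0.04,0.82
exposure,0.33,0.29,0.04,0.79
mirtazapine,0.33,0.28,0.03,0.83
gcbt_heimberg,0.32,0.28,0.04,0.78
moclobemide,0.30,0.25,0.03,0.76
pregabalin,0.29,0.25,0.03,0.77
shns_internet,0.27,0.22,0.03,0.73
pdpt,0.26,0.21,0.03,0.72
pill_placebo,0.21,0.16,0.02,0.64
ipt,0.20,0.15,0.02,0.64
mindfulness,0.19,0.14,0.02,0.63
supportive,0.16,0.11,0.01,0.57
wait_list,0.10,0.07,0.01,0.39
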