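# Published probabilistic means (cost, QALYs, % well at 5 years, NMB rank at
# £20,000/QALY) for the 28 interventions, used as fixed inputs to the
# incremental-analysis checks.
published_means <- function() {
  read.csv(text = 'id,well,qaly,cost,rank
icbt_cw,50.25,3.75,6178,1
icbt_general,41.40,3.64,5714,2
icbt_hope,37.52,3.59,5853,6
icbt_short,36.25,3.57,5970,9
phenelzine,34.80,3.57,4557,3
shws_internet,34.02,3.54,5186,7
shws_book,33.59,3.54,4741,5
gcbt_general,33.54,3.54,5436,11
shns_book,33.28,3.53,4501,4
exposure,33.00,3.53,5448,14
gcbt_heimberg,32.40,3.52,5463,17
paroxetine,30.01,3.51,4561,8
venlafaxine,29.46,3.50,4633,10
fluvoxamine,29.08,3.50,4666,12
sertraline,28.75,3.49,4583,13
shns_internet,29.55,3.49,5042,20
escitalopram,28.12,3.48,4591,15
fluoxetine,27.98,3.48,4597,16
pdpt,28.80,3.48,6509,25
citalopram,27.53,3.47,4602,18
mirtazapine,27.18,3.47,4611,19
moclobemide,25.95,3.45,4740,21
pregabalin,25.78,3.45,4898,22
ipt,25.44,3.44,5987,27
mindfulness,24.86,3.43,5041,23
pill_placebo,22.29,3.40,4713,24
supportive,22.89,3.40,5934,28
wait_list,20.43,3.37,4593,26', stringsAsFactors = FALSE)
}
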