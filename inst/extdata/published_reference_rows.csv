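"event","level","a","ror","ror_ci_low","ror_ci_high","prr","chisq","ic","ic025","ebgm","ebgm05"
"Nervous system disorders","SOC",559,16.08,14.19,18.22,7.62,3470.01,2.93,2.78,7.62,6.86
"Amyloid related imaging abnormality-oedema/effusion","PT",148,74228.59,45823.13,120242.41,63209.85,1064336.22,12.81,12.48,7192.43,4803.87
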