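quantity,metric,reference_risk,reference_rr,local_risk,local_rr,informs
overall_wave1,risk,0.00187,NA,0.00177,NA,lg0
death,rr,0.90,744,0.76359,734,lg1
no_death,risk,0.00121,NA,0.00104,NA,
white,risk,0.00185,1,0.00047,1,
black,rr,0.00307,1.66,0.00118,2.48,la_Black
asian,rr,0.00257,1.39,0.00089,1.87,la_Asian
mixed_other,rr,0.00188,1.02,0.00054,1.14,la_Mixed/Other
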