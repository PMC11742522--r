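name,year_start,year_end,value,weight,tolerance
masld_prevalence,2001,2001,28.0,1,1.0
masld_prevalence,2020,2020,33.7,1,0.5
masld_prevalence,2030,2030,36.8,1,0.5
mash_share,2018,2018,17.2,1,0.5
mean_annual_hcc,2020,2025,11483,1,3500
mean_annual_lt,2020,2025,1717,1,550
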