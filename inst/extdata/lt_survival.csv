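"age_band","years_since_lt","annual_death_prob"
"18-49",0,0.1
"18-49",1,0.035
"18-49",2,0.03
"18-49",3,0.025
"18-49",4,0.025
"18-49",5,0.025
"18-49",6,0.025
"18-49",7,0.025
"18-49",8,0.025
"18-49",9,0.025
"18-49",10,0.025
"50-64",0,0.12
"50-64",1,0.045
"50-64",2,0.04
"50-64",3,0.035
"50-64",4,0.035
"50-64",5,0.035
"50-64",6,0.035
"50-64",7,0.035
"50-64",8,0.035
"50-64",9,0.035
"50-64",10,0.035
"65+",0,0.16
"65+",1,0.065
"65+",2,0.06
"65+",3,0.055
"65+",4,0.055
"65+",5,0.055
"65+",6,0.055
"65+",7,0.055
"65+",8,0.055
"65+",9,0.055
"65+",10,0.055
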