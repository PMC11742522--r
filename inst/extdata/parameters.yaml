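# Annual transition probabilities per person among model health states.
# Each entry: value, and where an uncertainty range is published, low/high.
# Calibrated quantities carry no range.
masl_f0_to_f1:    {value: 0.0662, low: 0.0556, high: 0.0766}
masl_f1_to_f0:    {value: 0.0458, low: 0.0371, high: 0.0543}
masl_f1_to_f2:    {value: 0.0741, low: 0.0634, high: 0.0848}
masl_f2_to_f1:    {value: 0.0778, low: 0.0638, high: 0.0916}
masl_f2_to_f3:    {value: 0.0690, low: 0.0557, high: 0.0821}
masl_f3_to_f2:    {value: 0.0948, low: 0.0806, high: 0.1088}
masl_f3_to_f4:    {value: 0.0605, low: 0.0489, high: 0.0720}
masl_f4_to_f3:    {value: 0.0768, low: 0.0557, high: 0.0974}
mash_f0_to_f1:    {value: 0.0984, low: 0.0644, high: 0.1312}
mash_f1_to_f0:    {value: 0.0428, low: 0.0284, high: 0.0569}
mash_f1_to_f2:    {value: 0.0981, low: 0.0772, high: 0.1186}
mash_f2_to_f1:    {value: 0.0638, low: 0.0452, high: 0.0821}
mash_f2_to_f3:    {value: 0.0907, low: 0.0689, high: 0.1120}
mash_f3_to_f2:    {value: 0.1269, low: 0.1046, high: 0.1485}
mash_f3_to_f4:    {value: 0.0779, low: 0.0599, high: 0.0957}
mash_f4_to_f3:    {value: 0.0766, low: 0.0519, high: 0.1007}
mash_onset:       {value: 0.0060}
mash_resolution:  {value: 0.0130}
f4_to_dc:         {value: 0.0268, low: 0.0250, high: 0.0286}
f3_to_hcc:        {value: 0.0011, low: 0.0004, high: 0.0018}
f4_to_hcc:        {value: 0.0022, low: 0.0016, high: 0.0027}
dc_to_hcc:        {value: 0.0011, low: 0.0008, high: 0.0027}
lt_rate:          {value: 0.0062}
dc_mortality:     {value: 0.0734, low: 0.0689, high: 0.0779}
hr_masld:         {value: 1.15}
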