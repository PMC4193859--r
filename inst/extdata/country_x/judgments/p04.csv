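criterion_a,criterion_b,ratio
bioterror,severity,0.808976
bioterror,economic,1.314292
bioterror,collaborate,1.931873
bioterror,epidemic,3.732132
severity,economic,1.624637
severity,collaborate,2.388048
severity,epidemic,4.613404
economic,collaborate,1.469896
economic,epidemic,2.839652
collaborate,epidemic,1.931873
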