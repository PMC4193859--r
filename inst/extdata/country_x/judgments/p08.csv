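criterion_a,criterion_b,ratio
bioterror,severity,0.773666
bioterror,economic,1.392129
bioterror,collaborate,2.219139
bioterror,epidemic,4.924578
severity,economic,1.799393
severity,collaborate,2.868343
severity,epidemic,6.365251
economic,collaborate,1.594061
economic,epidemic,3.537443
collaborate,epidemic,2.219139
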