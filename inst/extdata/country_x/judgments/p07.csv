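criterion_a,criterion_b,ratio
bioterror,severity,0.782346
bioterror,economic,1.372248
bioterror,collaborate,2.143547
bioterror,epidemic,4.594793
severity,economic,1.754016
severity,collaborate,2.739896
severity,epidemic,5.873095
economic,collaborate,1.56207
economic,epidemic,3.34837
collaborate,epidemic,2.143547
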