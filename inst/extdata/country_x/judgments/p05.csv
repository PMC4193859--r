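criterion_a,criterion_b,ratio
bioterror,severity,0.8
bioterror,economic,1.333333
bioterror,collaborate,2
bioterror,epidemic,4
severity,economic,1.666667
severity,collaborate,2.5
severity,epidemic,5
economic,collaborate,1.5
economic,epidemic,3
collaborate,epidemic,2
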