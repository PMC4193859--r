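criterion_a,criterion_b,ratio
bioterror,severity,0.818052
bioterror,economic,1.295522
bioterror,collaborate,1.866066
bioterror,epidemic,3.482202
severity,economic,1.583667
severity,collaborate,2.281109
severity,epidemic,4.2567
economic,collaborate,1.440397
economic,epidemic,2.687875
collaborate,epidemic,1.866066
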