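criterion_a,criterion_b,ratio
bioterror,severity,0.765082
bioterror,economic,1.412298
bioterror,collaborate,2.297397
bioterror,epidemic,5.278032
severity,economic,1.845944
severity,collaborate,3.002811
severity,epidemic,6.898648
economic,collaborate,1.626708
economic,epidemic,3.737193
collaborate,epidemic,2.297397
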