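criterion_a,criterion_b,ratio
bioterror,severity,0.836512
bioterror,economic,1.258783
bioterror,collaborate,1.741101
bioterror,epidemic,3.031433
severity,economic,1.504801
severity,collaborate,2.081383
severity,epidemic,3.623898
economic,collaborate,1.383162
economic,epidemic,2.408225
collaborate,epidemic,1.741101
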