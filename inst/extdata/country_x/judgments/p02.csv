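criterion_a,criterion_b,ratio
bioterror,severity,0.82723
bioterror,economic,1.277021
bioterror,collaborate,1.802501
bioterror,epidemic,3.24901
severity,economic,1.54373
severity,collaborate,2.178959
severity,epidemic,3.927575
economic,collaborate,1.411489
economic,epidemic,2.544211
collaborate,epidemic,1.802501
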