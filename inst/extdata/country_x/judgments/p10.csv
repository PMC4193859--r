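criterion_a,criterion_b,ratio
bioterror,severity,0.756593
bioterror,economic,1.43276
bioterror,collaborate,2.378414
bioterror,epidemic,5.656854
severity,economic,1.893699
severity,collaborate,3.143584
severity,epidemic,7.476744
economic,collaborate,1.660023
economic,epidemic,3.948222
collaborate,epidemic,2.378414
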