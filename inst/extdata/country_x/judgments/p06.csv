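criterion_a,criterion_b,ratio
bioterror,severity,0.791124
bioterror,economic,1.352651
bioterror,collaborate,2.07053
bioterror,epidemic,4.287094
severity,economic,1.709784
severity,collaborate,2.617201
severity,epidemic,5.418992
economic,collaborate,1.53072
economic,epidemic,3.169402
collaborate,epidemic,2.07053
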