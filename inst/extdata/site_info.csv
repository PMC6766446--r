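site,n_children,altitude_m,is_reference,fever_frac_median
BGD,187,8,0,0.066
INV,220,45,0,0.056
NEB,209,1400,0,0.047
PKN,207,30,0,0.108
BRF,133,16,1,0.005
PEL,196,120,0,0.042
TZH,129,1700,0,0.019
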