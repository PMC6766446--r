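site,outcome,prevalence
BGD,anemia,0.52
INV,anemia,0.55
NEB,anemia,0.50
PKN,anemia,0.88
BRF,anemia,0.40
PEL,anemia,0.55
TZH,anemia,0.62
BGD,low_ferritin,0.51
INV,low_ferritin,0.51
NEB,low_ferritin,0.51
PKN,low_ferritin,0.82
BRF,low_ferritin,0.51
PEL,low_ferritin,0.51
TZH,low_ferritin,0.51
BGD,high_tfr,0.35
INV,high_tfr,0.25
NEB,high_tfr,0.45
PKN,high_tfr,0.40
BRF,high_tfr,0.72
PEL,high_tfr,0.45
TZH,high_tfr,0.11
BGD,low_retinol,0.30
INV,low_retinol,0.25
NEB,low_retinol,0.20
PKN,low_retinol,0.45
BRF,low_retinol,0.06
PEL,low_retinol,0.30
TZH,low_retinol,0.61
BGD,low_zinc,0.25
INV,low_zinc,0.73
NEB,low_zinc,0.20
PKN,low_zinc,0.60
BRF,low_zinc,0.02
PEL,low_zinc,0.10
TZH,low_zinc,0.25
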