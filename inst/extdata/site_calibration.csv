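site,variable,mean,sd
BGD,ln_mpo,8.5,0.8
INV,ln_mpo,8.8,0.65
NEB,ln_mpo,8.5,0.74
PKN,ln_mpo,8.1,0.88
BRF,ln_mpo,8.0,1.2
PEL,ln_mpo,8.8,0.88
TZH,ln_mpo,8.2,0.76
BGD,ln_neo,6.8,0.82
INV,ln_neo,7.5,0.67
NEB,ln_neo,7.6,0.44
PKN,ln_neo,6.3,0.58
BRF,ln_neo,7.4,0.71
PEL,ln_neo,7.9,0.53
TZH,ln_neo,6.5,0.95
BGD,ln_aat,-1.0,0.61
INV,ln_aat,-1.1,0.65
NEB,ln_aat,-0.93,0.57
PKN,ln_aat,-2.0,0.78
BRF,ln_aat,-1.4,0.75
PEL,ln_aat,-0.84,0.59
TZH,ln_aat,-1.4,0.86
BGD,lmz,0.29,0.67
INV,lmz,0.84,0.67
NEB,lmz,0.062,0.8
PKN,lmz,0.68,0.84
BRF,lmz,0.039,0.74
PEL,lmz,1.0,0.54
TZH,lmz,0.39,1.3
BGD,manz,0.87,0.68
INV,manz,1.2,0.76
NEB,manz,0.66,0.87
PKN,manz,0.35,1.0
BRF,manz,0.016,0.78
PEL,manz,0.23,0.69
TZH,manz,-0.19,0.99
BGD,ln_agp,-0.0935,0.3246
INV,ln_agp,-0.0721,0.3524
NEB,ln_agp,0.1271,0.3323
PKN,ln_agp,-0.1009,0.4016
BRF,ln_agp,0.0417,0.3274
PEL,ln_agp,0.1165,0.3627
TZH,ln_agp,0.1296,0.3246
BGD,energy_kcal,240,120
INV,energy_kcal,580,250
NEB,energy_kcal,300,130
PKN,energy_kcal,460,230
BRF,energy_kcal,880,270
PEL,energy_kcal,510,180
TZH,energy_kcal,850,220
BGD,carb_pcte,64,6.8
INV,carb_pcte,61,6.5
NEB,carb_pcte,58,7.7
PKN,carb_pcte,53,8.7
BRF,carb_pcte,53,3.9
PEL,carb_pcte,70,5.7
TZH,carb_pcte,65,6.8
BGD,protein_pcte,12,1.9
INV,protein_pcte,11,1.6
NEB,protein_pcte,11,2.4
PKN,protein_pcte,11,2.0
BRF,protein_pcte,17,2.3
PEL,protein_pcte,11,2.2
TZH,protein_pcte,12,1.8
BGD,sqrt_iron,2.025,0.298
INV,sqrt_iron,1.844,0.142
NEB,sqrt_iron,1.897,0.306
PKN,sqrt_iron,1.817,0.377
BRF,sqrt_iron,3.742,0.598
PEL,sqrt_iron,2.429,0.520
TZH,sqrt_iron,2.775,0.228
BGD,sqrt_zinc,1.871,0.161
INV,sqrt_zinc,2.000,0.149
NEB,sqrt_zinc,1.871,0.199
PKN,sqrt_zinc,1.817,0.144
BRF,sqrt_zinc,3.033,0.394
PEL,sqrt_zinc,1.761,0.172
TZH,sqrt_zinc,2.345,0.079
BGD,sqrt_calcium,17.89,6.64
INV,sqrt_calcium,20.98,7.76
NEB,sqrt_calcium,18.17,5.78
PKN,sqrt_calcium,23.45,5.69
BRF,sqrt_calcium,33.17,2.24
PEL,sqrt_calcium,18.97,6.41
TZH,sqrt_calcium,22.14,7.29
BGD,sqrt_vit_a,13.78,4.53
INV,sqrt_vit_a,15.17,5.02
NEB,sqrt_vit_a,14.49,3.95
PKN,sqrt_vit_a,15.81,3.88
BRF,sqrt_vit_a,33.17,2.95
PEL,sqrt_vit_a,20.74,6.09
TZH,sqrt_vit_a,13.04,2.97
BGD,sqrt_vit_b6,0.894,0.121
INV,sqrt_vit_b6,0.632,0.118
NEB,sqrt_vit_b6,0.775,0.096
PKN,sqrt_vit_b6,0.837,0.179
BRF,sqrt_vit_b6,1.095,0.214
PEL,sqrt_vit_b6,0.707,0.106
TZH,sqrt_vit_b6,0.316,0.097
BGD,sqrt_folate,10.49,1.70
INV,sqrt_folate,10.95,1.04
NEB,sqrt_folate,10.95,1.93
PKN,sqrt_folate,9.75,1.45
BRF,sqrt_folate,13.42,1.13
PEL,sqrt_folate,9.64,1.34
TZH,sqrt_folate,8.31,0.90
BGD,sqrt_vit_b12,1.225,0.385
INV,sqrt_vit_b12,0.837,0.309
NEB,sqrt_vit_b12,1.140,0.374
PKN,sqrt_vit_b12,1.225,0.385
BRF,sqrt_vit_b12,2.258,0.117
PEL,sqrt_vit_b12,1.304,0.371
TZH,sqrt_vit_b12,1.304,0.469
BGD,sqrt_vit_c,6.000,2.10
INV,sqrt_vit_c,3.606,0.43
NEB,sqrt_vit_c,4.359,1.31
PKN,sqrt_vit_c,4.359,1.21
BRF,sqrt_vit_c,10.95,1.50
PEL,sqrt_vit_c,10.49,4.26
TZH,sqrt_vit_c,2.324,0.80
BGD,sqrt_protein,5.477,0.434
INV,sqrt_protein,5.244,0.381
NEB,sqrt_protein,5.244,0.572
PKN,sqrt_protein,5.244,0.477
BRF,sqrt_protein,6.519,0.441
PEL,sqrt_protein,5.244,0.524
TZH,sqrt_protein,5.477,0.411
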