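locus,LG,Ho,He,N,PIC
BoSF2304b,C09,0.00,0.48,5,0.43
BoSF1740,C08,0.00,0.63,5,0.57
BoSF378,C08,0.00,0.72,4,0.65
BoSF2680,C08,0.00,0.78,5,0.73
BoSF2054,C06,0.00,0.52,3,0.41
BoSF1215,C06,0.00,0.59,6,0.54
BoSF250,C06,0.00,0.67,3,0.58
BoSF2505,C06,0.00,0.60,4,0.54
BoSF2374,C05,0.00,0.62,4,0.54
BoSF1846,C05,0.00,0.69,4,0.62
BoSF2878,C05,0.00,0.57,3,0.48
BoSF912,C01,0.00,0.72,6,0.67
BoSF063,C01,0.00,0.74,8,0.69
BoSF2294a,C02,0.19,0.73,6,0.67
BoSF2615,C02,0.00,0.61,4,0.55
BoSF1167,C02,0.00,0.79,6,0.75
BoSF2248,C03,0.00,0.60,5,0.55
BoSF2232,C03,0.03,0.49,3,0.38
BoSF184,C04,0.00,0.73,7,0.68
BoSF1640,C09,0.00,0.43,2,0.33
BoSF2612,C08,0.00,0.67,4,0.59
BoSF2860,C07,0.04,0.76,8,0.71
BoSF2345,C01,0.00,0.76,5,0.71
BoSF1207,C01,0.07,0.77,8,0.73
BoSF042,C03,0.00,0.73,6,0.68
BoSF062,C03,0.03,0.51,5,0.46
BoSF2985,C03,0.00,0.68,4,0.60
BoE862,C04,0.00,0.75,6,0.70
BRAS011,C02,0.03,0.77,10,0.73
BrBAC214,C03,0.00,0.48,5,0.43
BoESSR080,C07,0.03,0.78,9,0.73
BoESSR086,C03,0.00,0.63,6,0.58
BoESSR087,C04,0.00,0.70,5,0.65
BoESSR089,C01,0.00,0.80,7,0.76
BoESSR105,C04,0.00,0.76,6,0.71
BoESSR108,C04,0.00,0.67,5,0.60
BoESSR122,C02,0.00,0.82,8,0.78
BoESSR151,C02,0.00,0.70,6,0.65
BoESSR206,C05,0.00,0.53,4,0.47
BoESSR207,C05,0.00,0.78,5,0.72
BoESSR208,C04,0.00,0.71,8,0.66
BoESSR212,C07,0.00,0.56,4,0.51
BoESSR216,C01,0.00,0.76,5,0.70
BoESSR248,C04,0.00,0.62,5,0.57
BoESSR303,C04,0.00,0.33,4,0.31
BoESSR333,C04,0.00,0.81,9,0.77
BoESSR338,C08,0.00,0.77,8,0.72
BoESSR403,C08,0.00,0.72,7,0.66
BoESSR409,C04,0.00,0.78,6,0.73
BoESSR576,C06,0.00,0.71,6,0.65
BoESSR581,C06,0.00,0.67,7,0.62
BoESSR632,C01,0.00,0.71,6,0.67
BoESSR901,C09,0.00,0.77,7,0.73
BoESSR766,C03,0.00,0.69,7,0.63
BoESSR825,,0.00,0.69,7,0.63
BoESSR673,C03,0.00,0.66,5,0.58
BoESSR758,C07,0.00,0.68,7,0.64
BoESSR763,C04,0.00,0.80,8,0.76
BoESSR863,C06,0.00,0.69,4,0.62
BoESSR903,C06,0.00,0.50,5,0.46
Na12F03a,C07,0.07,0.83,8,0.80
O110B11,C05,0.00,0.65,4,0.57
BoSF2406,C07,0.03,0.67,7,0.62
BoSF2313,C07,0.07,0.75,8,0.70
BoSF2033,C07,0.00,0.81,9,0.77
BoSF317,C05,0.00,0.70,6,0.66
BoSF2421,C09,0.03,0.61,6,0.57
BoSF1957,C04,0.00,0.82,8,0.77
Na12B09,C03,0.00,0.70,6,0.66
cnu107,C02,0.00,0.27,3,0.24
BoSF1131,C03,0.00,0.78,7,0.73
BoSF966,C03,0.00,0.80,7,0.75
CB10258,C01,0.00,0.78,8,0.73
BoESSR920,C09,0.00,0.79,6,0.73
BoESSR041,C06,0.00,0.83,8,0.79
BoESSR934,C08,0.00,0.65,4,0.57
Ni4D12,C02,0.00,0.57,3,0.48
cnu149,C05,0.00,0.81,8,0.76
BoESSR482,C02,0.00,0.79,7,0.75
O112G04a,C08,0.00,0.44,4,0.40
BoESSR492,C03,0.00,0.76,8,0.72
BoESSR510,C03,0.00,0.59,4,0.51
BoESSR523,C07,0.00,0.76,7,0.71
BoESSR560,C03,0.00,0.73,6,0.67
BoESSR736,C05,0.00,0.66,5,0.61
BoESSR030,C03,0.00,0.76,8,0.71
BoESSR073,C03,0.00,0.50,6,0.46
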