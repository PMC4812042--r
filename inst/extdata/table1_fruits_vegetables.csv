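item,mu_A,mu_B,mu_AorB
Almond,0.0359,0.0133,0.0269
Acorn,0.0425,0.0108,0.0249
Peanut,0.0372,0.0220,0.0269
Olive,0.0586,0.0269,0.0415
Coconut,0.0755,0.0125,0.0604
Raisin,0.1026,0.0170,0.0555
Elderberry,0.1138,0.0170,0.0480
Apple,0.1184,0.0155,0.0688
Mustard,0.0149,0.0250,0.0146
Wheat,0.0136,0.0255,0.0165
Root Ginger,0.0157,0.0323,0.0385
Chili Pepper,0.0167,0.0446,0.0323
Garlic,0.0100,0.0301,0.0293
Mushroom,0.0140,0.0545,0.0604
Watercress,0.0112,0.0658,0.0482
Lentils,0.0095,0.0713,0.0338
Green Pepper,0.0324,0.0788,0.0506
Yam,0.0533,0.0724,0.0541
Tomato,0.0881,0.0679,0.0688
Pumpkin,0.0797,0.0713,0.0579
Broccoli,0.0143,0.1284,0.0642
Rice,0.0140,0.0412,0.0248
Parsley,0.0155,0.0266,0.0308
Black Pepper,0.0127,0.0294,0.0222
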