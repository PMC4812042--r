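item,x,y
Almond,-7.2826,3.24347
Acorn,-7.3316,2.3116
Peanut,-5.2957,4.56032
Olive,-4.3776,3.41765
Coconut,-5.0322,1.24573
Raisin,-2.7149,0.896651
Elderberry,-1.420,0.487598
Apple,0,0
Mustard,1.7978,7.64549
Wheat,2.4786,7.73915
Root Ginger,2.8164,7.41004
Chili Pepper,3.9933,7.03549
Garlic,4.7681,7.81803
Mushroom,5.6281,6.89107
Watercress,7.233,6.67322
Lentils,8.1373,6.56281
Green Pepper,3.8337,5.55379
Yam,1.5305,4.69497
Tomato,2.4348,2.42612
Pumpkin,3.9873,2.06652
Broccoli,10,4
Rice,11.6771,0.392458
Parsley,11.3949,-0.268463
Black Pepper,11.9389,-0.107151
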