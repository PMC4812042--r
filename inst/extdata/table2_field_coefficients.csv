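monomial,F
1,87.6039
x,2792.02
y,8425.01
x^2,19.36
x*y,-2139.87
y^2,-7322.26
x^3,-39.2811
x^2*y,-55.5263
x*y^2,586.674
y^3,2205.81
x^4,-2.22868
x^3*y,4.19408
x^2*y^2,13.3579
x*y^3,-72.233
y^4,-275.834
x^5,0.426731
x^4*y,1.58764
x^3*y^2,0.582536
x^2*y^3,-1.13167
x*y^4,3.44008
y^5,12.2584
x^6,-0.00943132
x^5*y,-0.0535881
x^4*y^2,-0.200688
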