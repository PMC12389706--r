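# Embedded atomic constants; see ?element_data for column meanings
symbol,Z,A,I,k_edge,omega_K,e_Kx,f_K,l_edge,X0
H,1,1.008,19.2,0.0136,0.0000,0.0105,1.00,0.0136,63.799058
C,6,12.011,78.0,0.2840,0.0028,0.2770,0.95,0.0100,43.008549
N,7,14.007,82.0,0.4100,0.0052,0.3920,0.95,0.0200,38.235466
O,8,15.999,95.0,0.5430,0.0083,0.5250,0.95,0.0280,34.458885
Na,11,22.990,149.0,1.0720,0.0230,1.0410,0.94,0.0630,27.972969
Mg,12,24.305,156.0,1.3050,0.0300,1.2540,0.94,0.0740,25.269766
P,15,30.974,173.0,2.1460,0.0630,2.0140,0.93,0.1320,21.474705
S,16,32.060,180.0,2.4720,0.0780,2.3080,0.93,0.1630,19.760733
Cl,17,35.450,174.0,2.8220,0.0970,2.6220,0.93,0.2000,19.561175
K,19,39.098,190.0,3.6070,0.1400,3.3140,0.92,0.2970,17.603587
Ca,20,40.078,191.0,4.0380,0.1630,3.6920,0.92,0.3460,16.426883
Fe,26,55.845,286.0,7.1120,0.3400,6.4040,0.89,0.7100,14.140208
Zn,30,65.380,330.0,9.6590,0.4740,8.6390,0.87,1.0200,12.721832
Bi,83,208.980,823.0,90.5260,0.9580,77.0000,0.78,13.4200,6.224162
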