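# ICRP-style tissue compositions (mass fractions); backing layer is pure water
layer,density,element,mass_fraction
epidermis,   1.09,H,0.100588
epidermis,   1.09,C,0.22825
epidermis,   1.09,N,0.04642
epidermis,   1.09,O,0.619002
epidermis,   1.09,Na,  7e-05
epidermis,   1.09,Mg,  6e-05
epidermis,   1.09,P,0.00033
epidermis,   1.09,S,0.00159
epidermis,   1.09,Cl,0.00267
epidermis,   1.09,K,0.00085
epidermis,   1.09,Ca,0.00015
epidermis,   1.09,Fe,  1e-05
epidermis,   1.09,Zn,  1e-05
dermis,      1,H,0.104472
dermis,      1,C,0.23219
dermis,      1,N,0.02488
dermis,      1,O,0.630238
dermis,      1,Na,0.00113
dermis,      1,Mg,0.00013
dermis,      1,P,0.00133
dermis,      1,S,0.00199
dermis,      1,Cl,0.00134
dermis,      1,K,0.00199
dermis,      1,Ca,0.00023
dermis,      1,Fe,  5e-05
dermis,      1,Zn,  3e-05
subcut,   0.92,H,0.119477
subcut,   0.92,C,0.63724
subcut,   0.92,N,0.00797
subcut,   0.92,O,0.232333
subcut,   0.92,Na, 0.0005
subcut,   0.92,Mg,  2e-05
subcut,   0.92,P,0.00016
subcut,   0.92,S,0.00073
subcut,   0.92,Cl,0.00119
subcut,   0.92,K,0.00032
subcut,   0.92,Ca,  2e-05
subcut,   0.92,Fe,  2e-05
subcut,   0.92,Zn,  2e-05
muscle,   1.05,H,0.100637
muscle,   1.05,C,0.10783
muscle,   1.05,N,0.02768
muscle,   1.05,O,0.754773
muscle,   1.05,Na,0.00075
muscle,   1.05,Mg,0.00019
muscle,   1.05,P, 0.0018
muscle,   1.05,S,0.00241
muscle,   1.05,Cl,0.00079
muscle,   1.05,K,0.00302
muscle,   1.05,Ca,  3e-05
muscle,   1.05,Fe,  4e-05
muscle,   1.05,Zn,  5e-05
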