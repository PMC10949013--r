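symbol,Z,chi_pauling,outer_shell_e,period,valence_e,vep,epsilon,oxidation_state_common
O,8,3.44,6,2,6,NA,0,-2
Li,3,0.98,1,2,1,18.95,0.98,1
Na,11,0.93,1,3,1,14.12,0.93,1
K,19,0.82,1,4,1,10.43,0.82,1
Mg,12,1.31,2,3,2,40.00,1.31,2
Ca,20,1.00,2,4,2,28.80,1.00,2
Sr,38,0.95,2,5,2,24.41,0.95,2
Ba,56,0.89,2,6,2,21.33,0.89,2
Al,13,1.61,3,3,3,80.74,1.61,3
Ga,31,1.81,3,4,3,69.67,1.81,3
In,49,1.78,3,5,3,54.00,1.78,3
Sn,50,1.96,4,5,4,83.47,1.96,4
Sb,51,2.05,5,5,5,56.84,0.3354102,3
Bi,83,2.02,5,6,5,41.94,2.02,3
Sc,21,1.36,2,4,3,57.99,1.36,3
Ti,22,1.54,2,4,4,95.20,1.54,4
V,23,1.63,2,4,5,133.32,1.63,5
Cr,24,1.66,1,4,6,70.24,1.66,3
Mn,25,1.55,2,4,7,220,1.55,4
Fe,26,1.83,2,4,8,66.97,1.83,3
Co,27,1.88,2,4,9,38,1.88,2
Ni,28,1.91,2,4,10,41.74,1.91,2
Cu,29,1.90,1,4,11,39.45,6.3023805,2
Zn,30,1.65,2,4,2,38.92,1.65,2
Y,39,1.22,2,5,3,48.00,1.22,3
Zr,40,1.33,2,5,4,80.00,1.33,4
Nb,41,1.60,1,5,5,112.49,1.60,5
Mo,42,2.16,1,5,6,146.43,2.16,6
W,74,2.36,2,6,6,144.00,2.36,6
La,57,1.10,2,6,3,41.94,1.10,3
Ce,58,1.12,2,6,3,42.77,1.12,3
Gd,64,1.20,2,6,3,46.04,1.20,3
Yb,70,1.10,2,6,3,49.77,1.10,3
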