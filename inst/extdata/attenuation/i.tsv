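# Iodine (Z=53) mass attenuation coefficient, total; K edge 33.17 keV
# energy_keV	mu_rho_cm2_g
20	39.39
30	11.31
33.16	8.333
33.18	47.53
40	26.69
50	13.43
60	7.689
80	3.226
100	1.674
150	0.5526
200	0.2830
300	0.1403
400	0.1007
500	0.08329
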