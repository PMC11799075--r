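# Sodium (Z=11) mass attenuation coefficient, total
# energy_keV	mu_rho_cm2_g
20	1.662
30	0.6030
40	0.3459
50	0.2525
60	0.2092
80	0.1707
100	0.1529
150	0.1310
200	0.1185
300	0.1022
400	0.09141
500	0.08340
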