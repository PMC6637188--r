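# Photon linear-attenuation and mass energy-absorption coefficients.
# Compiled approximate reference values (XCOM-like) per material; units:
# E in keV, mu_over_rho and mu_en_over_rho in cm^2/g. Log-log interpolated.
E_keV,material,mu_over_rho,mu_en_over_rho
30,water,0.3756,0.1357
40,water,0.2683,0.0647
50,water,0.2269,0.0419
60,water,0.2059,0.0319
80,water,0.1837,0.0260
100,water,0.1707,0.02546
150,water,0.1505,0.02764
200,water,0.1370,0.02967
300,water,0.1186,0.03192
400,water,0.1061,0.03279
500,water,0.0969,0.03299
600,water,0.0896,0.03284
662,water,0.0857,0.03270
800,water,0.0786,0.03206
1000,water,0.0707,0.03103
1250,water,0.0632,0.02965
1500,water,0.0575,0.02833
30,air,0.3538,0.1501
40,air,0.2485,0.0668
50,air,0.2080,0.0406
60,air,0.1875,0.0305
80,air,0.1662,0.0243
100,air,0.1541,0.0234
150,air,0.1356,0.0250
200,air,0.1233,0.0268
300,air,0.1067,0.0288
400,air,0.0954,0.0296
500,air,0.0871,0.0297
600,air,0.0806,0.0296
662,air,0.0770,0.0294
800,air,0.0707,0.0289
1000,air,0.0636,0.0280
1250,air,0.0569,0.0267
1500,air,0.0518,0.0255
30,SiO2,0.8720,0.6400
40,SiO2,0.4650,0.2800
50,SiO2,0.3180,0.1500
60,SiO2,0.2515,0.0920
80,SiO2,0.1935,0.0480
100,SiO2,0.1684,0.0355
150,SiO2,0.1376,0.0290
200,SiO2,0.1255,0.0285
300,SiO2,0.1076,0.0292
400,SiO2,0.0964,0.0296
500,SiO2,0.0878,0.0297
600,SiO2,0.0812,0.0294
662,SiO2,0.0777,0.0292
800,SiO2,0.0713,0.0286
1000,SiO2,0.0640,0.0277
1250,SiO2,0.0574,0.0264
1500,SiO2,0.0523,0.0252
30,glass,0.8720,0.6400
40,glass,0.4650,0.2800
50,glass,0.3180,0.1500
60,glass,0.2515,0.0920
80,glass,0.1935,0.0480
100,glass,0.1684,0.0355
150,glass,0.1376,0.0290
200,glass,0.1255,0.0285
300,glass,0.1076,0.0292
400,glass,0.0964,0.0296
500,glass,0.0878,0.0297
600,glass,0.0812,0.0294
662,glass,0.0777,0.0292
800,glass,0.0713,0.0286
1000,glass,0.0640,0.0277
1250,glass,0.0574,0.0264
1500,glass,0.0523,0.0252
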