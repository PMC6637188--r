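# Collision (electronic) stopping power of liquid water for electrons.
# Compiled approximate reference values (ESTAR-like); units: E in keV,
# S in MeV cm^2/g. Used with log-log interpolation; CSDA ranges are
# obtained by numerical integration of 1/S from the 1 keV cutoff.
E_keV,S_MeV_cm2_g
1,105.0
2,63.5
3,49.5
4,41.0
5,35.3
6,31.5
8,26.0
10,22.56
15,16.47
20,13.17
30,9.653
40,7.777
50,6.603
60,5.797
80,4.757
100,4.115
150,3.238
200,2.793
300,2.355
400,2.148
500,2.034
600,1.963
700,1.915
800,1.886
900,1.863
1000,1.849
1250,1.833
1500,1.822
2000,1.824
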