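system,pair,label,chain,occupancy
6z0g_TD,K26/D16,NZ-OD1,A,34.74
6z0g_TD,K26/D16,NZ-OD2,A,44.57
6z0g_TD,K26/T20,NZ-OG1,A,15.10
6z0g_TD,W34/T20,NE1-OG1,A,0
6z0g_TD,W34/T20,NE1-O,A,0
6z0g_TD,K26/D16,NZ-OD1,B,0
6z0g_TD,K26/D16,NZ-OD2,B,0
6z0g_TD,K26/T20,NZ-OG1,B,0.52
6z0g_TD,W34/T20,NE1-OG1,B,0
6z0g_TD,W34/T20,NE1-O,B,0
6z0i_TD,K26/D16,NZ-OD1,A,24.85
6z0i_TD,K26/D16,NZ-OD2,A,60.35
6z0i_TD,K26/T20,NZ-OG1,A,0
6z0i_TD,W34/T20,NE1-OG1,A,0
6z0i_TD,W34/T20,NE1-O,A,0
6z0i_TD,K26/D16,NZ-OD1,B,34.91
6z0i_TD,K26/D16,NZ-OD2,B,43.03
6z0i_TD,K26/T20,NZ-OG1,B,0
6z0i_TD,W34/T20,NE1-OG1,B,0
6z0i_TD,W34/T20,NE1-O,B,0
AF_TD,K26/D16,NZ-OD1,A,32.86
AF_TD,K26/D16,NZ-OD2,A,38.49
AF_TD,K26/T20,NZ-OG1,A,0
AF_TD,W34/T20,NE1-OG1,A,0.55
AF_TD,W34/T20,NE1-O,A,9.08
AF_TD,K26/D16,NZ-OD1,B,33.29
AF_TD,K26/D16,NZ-OD2,B,34.78
AF_TD,K26/T20,NZ-OG1,B,1.02
AF_TD,W34/T20,NE1-OG1,B,0
AF_TD,W34/T20,NE1-O,B,0
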