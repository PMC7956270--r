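# Atomic number densities (atoms per cubic Angstrom) of water-methanol mixtures
# from NpT molecular dynamics (TIP4P/2005 water), room temperature.
# comment column flags two suspicious cells; see the column itself.
x_methanol,pressure_GPa,number_density,comment
0.0,0.15,0.1074,
0.1,0.15,0.1044,
0.2,0.15,0.1034,
0.3,0.15,0.1025,
0.4,0.15,0.1019,
0.5,0.15,0.1009,
0.6,0.15,0.1001,
0.7,0.15,0.0994,
0.8,0.15,0.0985,
0.9,0.15,0.0976,
1.0,0.15,0.0967,
0.0,0.4,0.1129,
0.1,0.4,0.1114,
0.2,0.4,0.1101,
0.3,0.4,0.1092,
0.4,0.4,0.1085,
0.5,0.4,0.1078,
0.6,0.4,0.1071,
0.7,0.4,0.1065,
0.8,0.4,0.1058,
0.9,0.4,0.1053,
1.0,0.4,0.1047,
0.0,0.8,0.1214,
0.1,0.8,0.1194,
0.2,0.8,0.1179,
0.3,0.8,0.1167,
0.4,0.8,0.1159,
0.5,0.8,0.1152,
0.6,0.8,0.1146,
0.7,0.8,0.1139,
0.8,0.8,0.1135,
0.9,0.8,0.1130,
1.0,0.8,0.1125,
0.0,1.2,0.1365,outlier: large jump vs 0.8 GPa (possible ice VI region); value retained as published
0.1,1.2,0.1252,
0.2,1.2,0.1236,
0.3,1.2,0.1224,
0.4,1.2,0.1214,
0.5,1.2,0.1206,
0.6,1.2,0.1200,corrected from apparent misprint 0.200 in the source table
0.7,1.2,0.1194,
0.8,1.2,0.1189,
0.9,1.2,0.1179,
1.0,1.2,0.1179,
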