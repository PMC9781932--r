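solute,solvent1,solvent2,x2_star,temp,temp_unit,x,u_x,source
A,DMSO,water,0,25,C,0.002,1e-4,measured
A,DMSO,water,0,30,C,0.0024,1e-4,measured
A,DMSO,water,0,35,C,0.0028000000000000004,1e-4,measured
A,DMSO,water,0,40,C,0.0032,1e-4,measured
A,DMSO,water,0.2,25,C,0.051699999999999996,5e-4,measured
A,DMSO,water,0.2,30,C,0.0722,0.0038,measured
A,DMSO,water,0.2,35,C,0.0998,0.0017000000000000001,measured
A,DMSO,water,0.2,40,C,0.1366,0.0051,measured
A,DMSO,water,0.4,25,C,0.1365,0.0037,measured
A,DMSO,water,0.4,30,C,0.1837,0.0021,measured
A,DMSO,water,0.4,35,C,0.2379,0.0092,measured
A,DMSO,water,0.4,40,C,0.3147,0.0115,measured
A,DMSO,water,0.6,25,C,0.2647,0.0089,measured
A,DMSO,water,0.6,30,C,0.3169,0.009899999999999999,measured
A,DMSO,water,0.6,35,C,0.3795,0.0067,measured
A,DMSO,water,0.6,40,C,0.4523,0.0079,measured
A,DMSO,water,0.8,25,C,0.3161,0.0095,measured
A,DMSO,water,0.8,30,C,0.3703,0.0096,measured
A,DMSO,water,0.8,35,C,0.4338,0.0054,measured
A,DMSO,water,0.8,40,C,0.5108,0.0078000000000000005,measured
A,DMSO,,1,25,C,0.303,0.0055000000000000005,measured
A,DMSO,,1,30,C,0.3576,0.0070999999999999995,measured
A,DMSO,,1,35,C,0.42219999999999996,0.0102,measured
A,DMSO,,1,40,C,0.4892,0.0062,measured
A,DMF,water,0.2,25,C,0.0599,0.0034999999999999996,measured
A,DMF,water,0.2,30,C,0.0765,0.0026,measured
A,DMF,water,0.2,35,C,0.0943,0.004,measured
A,DMF,water,0.2,40,C,0.11810000000000001,0.006500000000000001,measured
A,DMF,water,0.4,25,C,0.1613,0.0039000000000000003,measured
A,DMF,water,0.4,30,C,0.1938,0.0046,measured
A,DMF,water,0.4,35,C,0.23600000000000002,0.0118,measured
A,DMF,water,0.4,40,C,0.2888,0.0044,measured
A,DMF,water,0.6,25,C,0.3107,0.0028000000000000004,measured
A,DMF,water,0.6,30,C,0.3457,0.011899999999999999,measured
A,DMF,water,0.6,35,C,0.39039999999999997,0.0074,measured
A,DMF,water,0.6,40,C,0.4462,0.016,measured
A,DMF,water,0.8,25,C,0.35259999999999997,0.009000000000000001,measured
A,DMF,water,0.8,30,C,0.3858,0.0055000000000000005,measured
A,DMF,water,0.8,35,C,0.4315,0.011899999999999999,measured
A,DMF,water,0.8,40,C,0.49310000000000004,0.013999999999999999,measured
A,DMF,,1,25,C,0.2869,0.006,measured
A,DMF,,1,30,C,0.3185,0.005600000000000001,measured
A,DMF,,1,35,C,0.3614,0.0068000000000000005,measured
A,DMF,,1,40,C,0.42729999999999996,0.0046,measured
A,4FM,water,0.2,25,C,0.0518,0.0034000000000000002,measured
A,4FM,water,0.2,30,C,0.071,0.0038,measured
A,4FM,water,0.2,35,C,0.0956,0.0026,measured
A,4FM,water,0.2,40,C,0.12539999999999998,0.0070999999999999995,measured
A,4FM,water,0.4,25,C,0.09630000000000001,0.0019,measured
A,4FM,water,0.4,30,C,0.1307,0.0043,measured
A,4FM,water,0.4,35,C,0.1668,0.005,measured
A,4FM,water,0.4,40,C,0.2048,0.004699999999999999,measured
A,4FM,water,0.6,25,C,0.1297,0.005,measured
A,4FM,water,0.6,30,C,0.1689,0.0028000000000000004,measured
A,4FM,water,0.6,35,C,0.2158,0.008199999999999999,measured
A,4FM,water,0.6,40,C,0.2616,0.0085,measured
A,4FM,water,0.8,25,C,0.15410000000000001,0.0046,measured
A,4FM,water,0.8,30,C,0.1946,0.0055000000000000005,measured
A,4FM,water,0.8,35,C,0.2445,0.0084,measured
A,4FM,water,0.8,40,C,0.2954,0.0022,measured
A,4FM,,1,25,C,0.1673,0.0055000000000000005,measured
A,4FM,,1,30,C,0.20800000000000002,0.0073,measured
A,4FM,,1,35,C,0.2589,0.0027,measured
A,4FM,,1,40,C,0.3111,0.0073,measured
P,4FM,water,0.2,25,C,0.0059,3e-4,measured
P,4FM,water,0.2,30,C,0.0079,2e-4,measured
P,4FM,water,0.2,35,C,0.0108,5e-4,measured
P,4FM,water,0.2,40,C,0.0154,4e-4,measured
P,4FM,water,0.4,25,C,0.0253,1e-4,measured
P,4FM,water,0.4,30,C,0.0302,0.0014000000000000002,measured
P,4FM,water,0.4,35,C,0.0364,0.0019,measured
P,4FM,water,0.4,40,C,0.0467,0.0016,measured
P,4FM,water,0.6,25,C,0.04190000000000001,9e-4,measured
P,4FM,water,0.6,30,C,0.048,1e-4,measured
P,4FM,water,0.6,35,C,0.057800000000000004,0.0022,measured
P,4FM,water,0.6,40,C,0.0711,0.0032,measured
P,4FM,water,0.8,25,C,0.0533,7.000000000000001e-4,measured
P,4FM,water,0.8,30,C,0.0603,0.0015,measured
P,4FM,water,0.8,35,C,0.0694,0.0017000000000000001,measured
P,4FM,water,0.8,40,C,0.08199999999999999,7.000000000000001e-4,measured
P,4FM,,1,25,C,0.061900000000000004,0.0018,measured
P,4FM,,1,30,C,0.0689,0.0014000000000000002,measured
P,4FM,,1,35,C,0.079,0.0013,measured
P,4FM,,1,40,C,0.09119999999999999,0.0021,measured
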