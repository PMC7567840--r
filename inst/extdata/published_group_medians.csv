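shortcut,protocol,control_median,mild_median,mild_diff_pct,severe_median,severe_diff_pct
FAwS,hardi_zoomit_interp,0.1422,0.1286,-9.60,0.1356,-4.65
FAwK,hardi_zoomit_interp,2.4934,2.8241,13.26,2.6698,7.07
f1wS,hardi_zoomit_interp,0.1512,0.1323,-12.55,0.1397,-7.61
f1wSK,hardi_zoomit_interp,-0.1315,-0.0805,-38.82,0.0313,-123
f1wK,hardi_zoomit_interp,2.4683,2.7209,10.23,2.7330,10.72
MDwM,hardi_zoomit_interp,1.0509,0.9951,-5.31,1.0578,0.65
MDwm,hardi_zoomit_interp,1.1545,1.0576,-8.39,1.1005,-4.68
MDwS,hardi_zoomit_interp,0.3561,0.2621,-26.39,0.2863,-19.60
dwS,hardi_zoomit_interp,0.4893,0.4325,-11.62,0.4545,-7.11
dwSK,hardi_zoomit_interp,1.1506,1.1119,-3.36,0.9342,-18.80
MDgM,hardi_zoomit_interp,0.8300,0.8406,1.28,0.8933,7.64
MDgm,hardi_zoomit_interp,0.8573,0.8633,0.70,0.9048,5.53
MDgSK,hardi_zoomit_interp,1.6110,1.4599,-9.38,1.2434,-22.81
dgM,hardi_zoomit_interp,1.4979,1.5211,1.55,1.6111,7.56
dgm,hardi_zoomit_interp,1.5401,1.5595,1.26,1.6498,7.13
MDwgM,hardi_zoomit_interp,0.2122,0.1470,-30.71,0.1711,-19.35
MDwgm,hardi_zoomit_interp,0.2803,0.1906,-32.00,0.1990,-29.00
dwgM,hardi_zoomit_interp,0.5129,0.4339,-15.41,0.4122,-19.63
dwgm,hardi_zoomit_interp,0.5676,0.4580,-19.31,0.4321,-23.87
FAwH,hardi_zoomit_interp,0.4729,0.5076,7.36,0.5349,13.13
f1wH,hardi_zoomit_interp,0.5362,0.5819,8.52,0.5897,9.98
MDwH,hardi_zoomit_interp,0.5683,0.6706,17.99,0.6403,12.67
dwH,hardi_zoomit_interp,0.5002,0.5513,10.21,0.5023,0.43
MDgH,hardi_zoomit_interp,0.4956,0.5400,8.96,0.5892,18.90
dgH,hardi_zoomit_interp,0.4872,0.4550,-6.60,0.3537,-27.41
FAwS,dti_resolve_noninterp,0.1266,0.1239,-2.11,0.1325,4.72
FAwK,dti_resolve_noninterp,2.7666,2.8592,3.35,2.7658,-0.03
f1wS,dti_resolve_noninterp,0.1398,0.1318,-5.71,0.1304,-6.75
f1wSK,dti_resolve_noninterp,-0.0685,-0.0078,-88.68,0.1390,-303
f1wK,dti_resolve_noninterp,2.6254,2.6115,-0.53,2.7310,4.02
MDwM,dti_resolve_noninterp,1.1614,1.1860,2.12,1.2524,7.83
MDwm,dti_resolve_noninterp,1.2414,1.2345,-0.56,1.3230,6.58
MDwS,dti_resolve_noninterp,0.3069,0.2708,-11.76,0.3150,2.64
dwS,dti_resolve_noninterp,0.3727,0.3544,-4.89,0.4238,13.72
dwSK,dti_resolve_noninterp,0.1457,0.2125,45.86,0.2112,44.99
MDgM,dti_resolve_noninterp,1.0577,1.1145,5.37,1.1772,11.29
MDgm,dti_resolve_noninterp,1.0657,1.1255,5.61,1.1975,12.37
MDgSK,dti_resolve_noninterp,0.0600,0.5163,760,0.6187,931
dgM,dti_resolve_noninterp,1.9277,1.9717,2.29,2.0262,5.11
dgm,dti_resolve_noninterp,1.8827,1.9816,5.26,2.0449,8.62
MDwgM,dti_resolve_noninterp,0.1185,0.0913,-23.00,0.1032,-12.94
MDwgm,dti_resolve_noninterp,0.1676,0.1172,-30.09,0.1244,-25.82
dwgM,dti_resolve_noninterp,0.3864,0.3446,-10.82,0.2546,-34.11
dwgm,dti_resolve_noninterp,0.3823,0.3340,-12.64,0.2373,-37.92
FAwH,dti_resolve_noninterp,0.5467,0.5569,1.87,0.5412,-1.00
f1wH,dti_resolve_noninterp,0.5789,0.5941,2.64,0.5505,-4.90
MDwH,dti_resolve_noninterp,0.5432,0.5755,5.94,0.4757,-12.42
dwH,dti_resolve_noninterp,0.3799,0.3538,-6.86,0.3411,-10.22
MDgH,dti_resolve_noninterp,0.7732,0.7345,-5.00,0.6435,-16.78
dgH,dti_resolve_noninterp,0.0774,0.0533,-31.08,0.0527,-31.82
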