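lat_min	lat_max	lon_min	lon_max	code
-90	-60	-180	-120	BWh
-60	-30	-180	-120	Aw
-30	0	-180	-120	ET
0	30	-180	-120	ET
30	60	-180	-120	Dfb
60	90	-180	-120	Cfb
-90	-60	-120	-60	BWh
-60	-30	-120	-60	BWh
-30	0	-120	-60	OCEAN
0	30	-120	-60	ET
30	60	-120	-60	BWh
60	90	-120	-60	Aw
-90	-60	-60	0	Dfc
-60	-30	-60	0	OCEAN
-30	0	-60	0	OCEAN
0	30	-60	0	Af
30	60	-60	0	EF
60	90	-60	0	Cfb
-90	-60	0	60	EF
-60	-30	0	60	Cfb
-30	0	0	60	Cfb
0	30	0	60	Cfb
30	60	0	60	Cfb
60	90	0	60	BSk
-90	-60	60	120	BWh
-60	-30	60	120	BSk
-30	0	60	120	Csa
0	30	60	120	ET
30	60	60	120	EF
60	90	60	120	Dfc
-90	-60	120	180	BSk
-60	-30	120	180	Dfc
-30	0	120	180	Aw
0	30	120	180	BSk
30	60	120	180	Dfc
60	90	120	180	OCEAN
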