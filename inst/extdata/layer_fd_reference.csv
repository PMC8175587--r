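layer,name,fd_ad,fd_ctl
1,NFL,2.1074,2.1018
2,GCL,2.1033,2.1012
3,IPL,2.1136,2.1110
4,INL,2.1105,2.1078
5,OPL,2.1180,2.1169
6,ONL,2.0939,2.0885
7,IS/OS,2.1281,2.1278
8,OSL,2.1217,2.1219
9,OPR,2.1230,2.1219
10,RPE,2.1269,2.1232
0,Total,2.0782,2.0800
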