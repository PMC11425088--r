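scorer,activecomm,activecomm,activecomm,activecomm,activecomm,activecomm
bodyparts,head,head,head,tailbase,tailbase,tailbase
coords,x,y,likelihood,x,y,likelihood
0,196.397,  157.4,      1,146.611,188.892,      1
1,211.524,157.128,      1,153.202,181.338,      1
2,220.303, 157.98,0.585371,162.556,174.266,0.602134
3,229.015,155.299,      1,171.377,172.341,      1
4,237.778,149.148,      1, 184.28,171.293,      1
5,249.294,146.405,      1,191.863,168.042,      1
6,258.932,145.849,      1,200.395,161.352,      1
7,269.251,141.162,      1,212.241,159.516,      1
8,278.269,143.565,0.23684,219.179,153.974,0.22167
9,288.422,136.703,      1,228.451,155.204,      1
10, 295.04,133.268,      1,239.035,  150.6,      1
11,304.779,127.585,0.428325,249.436,150.761,0.189516
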