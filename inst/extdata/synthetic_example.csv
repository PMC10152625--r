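"y","x1","x2","x3","x4","x5"
0,1,1,1.3764,1.2291,-0.1612
1,1,1,0.4689,2.6286,0.9954
1,0,2,-1.619,0.9848,-1.8784
0,0,1,-0.6613,0.1885,0.5628
1,0,1,-0.7589,3.1221,0.2708
0,1,1,-0.2239,0.7665,-2.5982
1,1,4,1.4826,3.2911,-3.0147
0,1,2,0.4489,1.5403,0.062
0,0,1,-0.0527,0.4253,-0.7414
1,0,2,-1.9578,0.2861,-0.5754
1,0,0,0.2256,0.3033,-0.2226
1,0,3,-0.3898,1.2244,0.583
1,0,1,0.6591,1.4978,0.3823
0,0,2,-0.1551,2.2699,-1.4122
1,1,0,-1.4433,0.2112,0.3816
1,0,1,-0.7458,4.0508,-0.0026
0,0,0,-0.9646,6.6805,0.1215
1,0,1,0.5818,2.577,-0.4371
1,0,0,-0.44,0.9935,2.0318
0,1,2,0.7116,6.6069,1.6019
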