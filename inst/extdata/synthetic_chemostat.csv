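mu,q_s
0.005,3.411
0.01,3.6535
0.015,4.0953
0.02,4.5261
0.025,4.9148
0.03,5.3326
0.035,5.8341
0.04,6.2075
0.045,6.6376
0.05,7.1562
0.055,7.4812
0.06,8.0158
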