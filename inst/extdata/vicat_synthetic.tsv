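time_min	depth_mm
0	18.0
5	12.5
10	6.0
15	2.0
20	0.0
25	0.0
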