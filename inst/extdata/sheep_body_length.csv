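sheep_id,tape_cm,cloud_cm
1,67.1,66.0
2,64.8,64.0
3,67.6,67.5
4,70.4,71.0
5,62.6,62.0
6,70.7,70.5
7,74.1,74.0
8,60.6,60.0
9,62.8,62.0
10,67.3,67.0
11,62.4,62.5
12,64.7,64.0
13,68.1,67.5
14,60.7,60.5
15,66.5,66.0
16,64.9,64.0
17,65.2,64.5
18,63.0,62.7
19,64.3,64.0
20,63.7,63.0
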