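11.9,19,24,24.7,22.7,20.6,19.1,17.1,14
14.6,24,31.7,34.9,35,34.7,33.7,30.5,24.8
14.5,24.7,34.9,42.6,48.2,52.3,53.1,48.8,39.6
12.7,22.7,35,48.2,60.9,70.8,74.1,68.6,55.7
11.1,20.6,34.7,52.3,70.8,85.3,90.8,84.4,68.5
10,19.1,33.7,53.1,74.1,90.8,97.1,90.5,73.4
8.9,17.1,30.5,48.8,68.6,84.4,90.5,84.4,68.5
7.5,14,24.8,39.6,55.7,68.5,73.4,68.5,55.6
5.8,10.4,17.9,28.3,39.5,48.5,52,48.5,39.5
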