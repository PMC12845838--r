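hour,n_events,mean_duration_s
6,20,13.7
7,25,42.6
8,49,58.6
9,51,40.1
10,52,36.7
11,41,28.5
12,42,30.9
13,42,34.6
14,69,56.0
15,93,38.6
16,82,48.1
17,33,53.3
18,13,9.2
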