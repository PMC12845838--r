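pig,day,n_events,total_s,total_min,mean_s,max_s,sd_s,first_hour,last_hour
Pig 1,1,29,2133.4,35.6,73.6,254.2,70.7,7.5,16.2
Pig 1,2,35,2272.2,37.9,64.6,255.9,66.5,7.3,17.0
Pig 1,3,44,2285.2,38.1,51.9,195.5,53.9,7.1,17.1
Pig 1,4,64,2828.5,47.1,44.2,243.7,53.2,6.8,17.2
Pig 1,5,55,2327.3,38.8,42.3,192.2,43.4,7.2,17.9
Pig 1,6,59,2041.9,34.0,34.6,185.6,36.2,7.0,17.1
Pig 2,1,15,240.5,4.0,16.0,28.3,8.1,8.1,17.2
Pig 2,2,10,145.5,2.4,14.5,33.6,9.3,7.3,18.2
Pig 2,3,15,244.6,4.1,16.3,35.8,10.1,9.3,18.0
Pig 2,4,12,151.7,2.5,12.6,38.1,8.7,6.8,17.6
Pig 2,5,14,231.7,3.9,16.6,35.0,10.5,9.1,15.2
Pig 2,6,20,261.6,4.4,13.1,38.7,9.9,8.1,16.7
Pig 3,1,22,2108.3,35.1,95.8,337.4,114.4,8.1,8.1
Pig 3,2,25,2235.6,37.3,89.4,369.4,105.0,9.3,7.3
Pig 3,3,24,2388.9,39.8,99.5,333.5,100.1,10.1,9.3
Pig 3,4,27,560.5,9.3,20.8,114.1,24.8,8.7,6.8
Pig 3,5,73,1563.7,26.1,21.4,297.3,37.1,10.5,9.1
Pig 3,6,69,1345.6,22.4,19.5,330.1,42.5,9.9,8.1
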