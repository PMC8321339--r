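sequence_id,onset,offset,minima,clip_length
1.1,49,62,37 63 74,89
2.1,92,100,32 60 106,120
3.1,82,90,68 80 111,138
5.2,75,81,54 72 85,174
6.1,15,26,12 30 51,60
7.1,52,60,39 42 48,69
7.3,93,98,17 56 89,101
7.5,54,70,31 34 50,77
7.6,59,76,47 56 83,136
7.8,81,90,53 59 80,112
7.9,76,87,45 88 90,100
8.2,19,34,18 33 42,109
9.1,88,96,76 83 88,55
10.1,13,27,10 52 62,41
10.2,81,93,10 62 80,192
11.2,7,21,11 29 35,38
11.3,57,67,32 50,73
11.4,9,23,21 27 33,63
11.5,33,49,20 38 50,63
13.1,16,32,15 38 50,64
13.2,6,20,23 29 34,58
14.1,35,41,42,64
14.3,21,26,13 22 27,37
15.1,36,41,30 42 55,64
16.2,45,52,30 46 54,62
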