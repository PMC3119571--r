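homology_row,section,kinase,state,partner1,partner2,salt_bridge
1,aC-helix A-loop,ErbB4,inactive,E739,R841,TRUE
2,aC-helix A-loop,EGFR,active,E734,K851,TRUE
2,aC-helix A-loop,ErbB2,active,E766,K883,TRUE
2,aC-helix A-loop,ErbB4,active,E739,K856,TRUE
3,aC-helix A-loop,EGFR,active,D737,K836,FALSE
3,aC-helix A-loop,ErbB2,active,D769,R868,FALSE
3,aC-helix A-loop,ErbB4,inactive,D742,R841,FALSE
4,aC-helix A-loop,EGFR,active,E738,F832,FALSE
4,aC-helix A-loop,ErbB4,active,E743,F837,FALSE
5,aC-helix A-loop,EGFR,inactive,E738,K836,TRUE
5,aC-helix A-loop,ErbB4,inactive,E743,R841,TRUE
6,A-loop C-loop,ErbB2,inactive,G865,V842,FALSE
7,A-loop C-loop,ErbB4,inactive,G838,R817,FALSE
8,A-loop C-loop,EGFR,active,L834,R812,FALSE
8,A-loop C-loop,ErbB2,active,L866,R844,FALSE
8,A-loop C-loop,ErbB4,active,L839,R817,FALSE
9,A-loop C-loop,EGFR,inactive,L834,D813,FALSE
10,A-loop C-loop,EGFR,active,K836,V810,FALSE
10,A-loop C-loop,ErbB2,active,R868,V842,FALSE
10,A-loop C-loop,ErbB4,active,R841,V815,FALSE
11,A-loop C-loop,ErbB3,inactive,D838,R814,TRUE
12,A-loop C-loop,EGFR,active,E848,R812,TRUE
13,A-loop C-loop,EGFR,inactive,K851,R812,FALSE
14,C-loop C-loop,ErbB2,active,H843,D845,FALSE
14,C-loop C-loop,ErbB3,inactive,H813,N815,FALSE
15,C-loop C-loop,EGFR,inactive,R812,D813,TRUE
15,C-loop C-loop,ErbB2,inactive,R844,D845,FALSE
16,C-loop C-loop,EGFR,active,D813,R817,TRUE
16,C-loop C-loop,ErbB2,active,D845,R849,FALSE
16,C-loop C-loop,ErbB4,active,D818,R822,TRUE
17,C-loop C-loop,EGFR,active,D813,N818,FALSE
17,C-loop C-loop,ErbB3,inactive,N815,N820,FALSE
18,C-loop C-loop,EGFR,active,A815,N818,FALSE
18,C-loop C-loop,ErbB2,active,A847,N850,FALSE
18,C-loop C-loop,ErbB4,active,A820,N823,FALSE
18,C-loop C-loop,EGFR,inactive,A815,N818,FALSE
18,C-loop C-loop,ErbB2,inactive,A847,N850,FALSE
18,C-loop C-loop,ErbB3,inactive,A817,N820,FALSE
19,C-loop C-loop,ErbB2,active,A848,V851,FALSE
20,aC-helix,ErbB2,active,A763,S760,FALSE
21,aC-helix,ErbB2,active,E766,R756,FALSE
22,aC-helix,EGFR,active,E738,K721,TRUE
22,aC-helix,ErbB2,active,E770,K753,TRUE
22,aC-helix,ErbB4,active,E743,K726,TRUE
23,aC-helix,EGFR,inactive,M742,L753,FALSE
23,aC-helix,ErbB2,inactive,M774,L785,FALSE
23,aC-helix,ErbB4,inactive,M747,L758,FALSE
24,aC-helix,EGFR,active,A743,L679,FALSE
24,aC-helix,ErbB4,active,A748,Q684,FALSE
25,aC-helix,ErbB4,inactive,A748,R757,FALSE
26,A-loop,ErbB4,active,D836,K726,FALSE
26,A-loop,ErbB2,inactive,D863,K753,TRUE
26,A-loop,ErbB3,inactive,D833,K723,TRUE
26,A-loop,ErbB4,inactive,D836,K726,TRUE
27,A-loop,ErbB4,active,D836,T835,FALSE
28,A-loop,EGFR,active,L838,R808,FALSE
28,A-loop,ErbB2,active,L870,R840,FALSE
28,A-loop,ErbB4,active,L843,R813,FALSE
29,A-loop,ErbB2,active,D871,R840,FALSE
30,A-loop,ErbB3,inactive,D844,K853,TRUE
31,A-loop,ErbB4,active,K848,T873,FALSE
32,A-loop,EGFR,active,K843,D932,TRUE
32,A-loop,ErbB4,active,K848,D937,FALSE
33,A-loop,ErbB2,active,E876,R898,FALSE
34,A-loop,ErbB4,active,E849,K871,FALSE
35,A-loop,EGFR,active,Y845,Y867,FALSE
35,A-loop,ErbB4,active,Y850,F872,FALSE
36,A-loop,ErbB4,active,A852,R870,FALSE
37,A-loop,ErbB2,active,D880,R897,TRUE
37,A-loop,ErbB4,active,D853,R870,TRUE
37,A-loop,EGFR,inactive,E848,R865,TRUE
37,A-loop,ErbB2,inactive,D880,R897,TRUE
37,A-loop,ErbB4,inactive,D853,R870,TRUE
38,A-loop,ErbB4,inactive,G855,E730,FALSE
39,A-loop,ErbB2,inactive,K883,E757,FALSE
40,A-loop,ErbB4,inactive,K856,E844,TRUE
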