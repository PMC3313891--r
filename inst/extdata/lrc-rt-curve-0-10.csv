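k,time,surv
1,0,1
2,0.18,0.994
3,0.42,0.989
4,0.91,0.979
5,1.39,0.974
6,1.88,0.969
7,2.6,0.964
8,2.85,0.959
9,3.33,0.933
10,3.34,0.923
11,3.58,0.901
12,3.83,0.865
13,4.07,0.85
14,4.56,0.828
15,4.8,0.817
16,5.29,0.777
17,5.54,0.767
18,5.78,0.759
19,6.02,0.749
20,6.51,0.716
21,6.75,0.711
22,7.73,0.671
23,7.97,0.661
24,8.21,0.651
25,8.46,0.638
26,8.7,0.628
27,8.7,0.626
28,8.95,0.621
29,9.43,0.616
30,9.92,0.61
31,10,0.608
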