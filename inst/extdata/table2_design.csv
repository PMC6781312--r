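run_id,lot,A,B,C,D,E,F,G
1,ZL0518,15,400,20,19.9,5,10,3.2
2,SXAS,5,410,22.8,18.9,4.3,20,3.0
3,XAHX,5,400,20,20,3,10,3.0
4,YNZW,8.8,500,24,10,5,10,3.1
5,ZL0524,15,400,24,20,5,20,3.0
6,WHYC,5,400,22.2,20,5,10,3.1
7,YNYK,8.1,500,20,17.5,3,10,3.1
8,BCTG,15,455,22,14.5,4.1,13.4,3.1
9,ZL0518,15,500,24,10,3,20,3.1
10,BCTG,13.4,500,24,10,5,20,3.0
11,YNZZ,5,400,24,20,3,15.9,3.2
12,ZL0518,5,400,22,10,5,10,3.2
13,ZL1208,5,400,20,10,5,14.8,3.1
14,ZL0524,5,500,24,20,3.9,20,3.1
15,YNZW,5,500,20,20,3,20,3.0
16,SXAS,15,500,22.1,20,3,20,3.2
17,SXAS,5,400,24,10,5,20,3.0
18,WHYC,15,400,20,20,3,20,3.1
19,ZL1208,15,400,24,10,4.2,20,3.2
20,BCTG,15,433,24,15.2,3,20,3.0
21,ZL0120,15,500,22.1,20,3,20,3.2
22,BCTG,10.75,400,24,14.3,5,20,3.1
23,ZL1208,5,434,21.6,15.1,3.6,14,3.1
24,YNSS,15,400,20,10,5,20,3.0
25,SXAS,5,400,20,12.9,3,20,3.2
26,BCTG,5,486,24,10,3,20,3.2
27,ZL0518,5,400,24,10,3,10,3.1
28,YNSS,5.7,441,20,20,5,20,3.2
29,YNSS,15,500,20,20,5,10,3.0
30,ZL0120,5,500,21.4,10,5,20,3.1
31,ZL0518,15,400,24,10,4.2,20,3.2
32,YNSS,15,400,24,20,3,10,3.1
33,YNYK,15,500,20,20,5,20,3.1
34,WHYC,15,464,24,20,5,10,3.2
35,ZL0120,7.05,500,21.2,19.7,5,14.6,3.1
36,ZL0518,8.5,500,21.6,10.3,3.8,13.7,3.2
37,YNSS,5,500,24,20,3,10,3.0
38,YNYK,15,400,20,10,3,10,3.1
39,XAHX,15,400,20,20,5,10,3.2
40,XAHX,5,500,20,20,3.8,10,3.2
41,YNZW,11.5,478,20,13.6,4,20,3.0
42,ZL0120,15,500,20,10,3,10,3.0
43,ZL1208,10.75,400,24,14.3,5,20,3.1
44,XAHX,15,444,20,10,3,15.3,3.2
45,YNYK,15,500,20,10,5,10,3.2
46,YNSS,5,500,20,10,5,10,3.0
47,XAHX,5,500,24,15.2,5,15.4,3.2
48,WHYC,15,500,24,10.2,3,10,3.2
49,SXAS,9,400,24,20,4.2,10,3.0
50,ZL0120,9.6,400,22.2,10,3,16.2,3.0
51,WHYC,15,400,24,10,5,10,3.0
52,YNZW,5,400,20,12.9,3,20,3.2
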