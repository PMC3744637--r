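"n","r","r_corrected","calibration_seed"
3,0.02,0.6,20101130
3,0.05,1.8,20101130
3,0.1,1.8,20101130
3,0.166,1.8,20101130
3,0.25,1.8,20101130
3,0.35,1.8,20101130
3,0.5,1.8,20101130
4,0.02,0.4,20101130
4,0.05,0.5,20101130
4,0.1,0.7,20101130
4,0.166,0.95,20101130
4,0.25,1,20101130
4,0.35,1,20101130
4,0.5,1.5,20101130
4,0.75,1.5,20101130
5,0.02,0.4,20101130
5,0.05,0.5,20101130
5,0.1,0.7,20101130
5,0.166,0.95,20101130
5,0.25,1,20101130
5,0.35,1,20101130
5,0.5,1.5,20101130
5,0.75,1.5,20101130
6,0.02,0.3,20101130
6,0.05,0.5,20101130
6,0.1,0.7,20101130
6,0.166,0.95,20101130
6,0.25,1,20101130
6,0.35,1,20101130
6,0.5,1.5,20101130
6,0.75,1.5,20101130
8,0.02,0.2,20101130
8,0.05,0.35,20101130
8,0.1,0.65,20101130
8,0.166,0.95,20101130
8,0.25,1,20101130
8,0.35,1,20101130
8,0.5,1.5,20101130
8,0.75,1.5,20101130
8,1,1.8,20101130
11,0.02,0.15,20101130
11,0.05,0.35,20101130
11,0.1,0.5,20101130
11,0.166,0.7,20101130
11,0.25,1,20101130
11,0.35,1,20101130
11,0.5,1.5,20101130
11,0.75,1.5,20101130
11,1,1.8,20101130
11,1.3,1.8,20101130
15,0.02,0.15,20101130
15,0.05,0.2,20101130
15,0.1,0.35,20101130
15,0.166,0.55,20101130
15,0.25,0.85,20101130
15,0.35,1,20101130
15,0.5,1.5,20101130
15,0.75,1.5,20101130
15,1,1.8,20101130
15,1.3,1.8,20101130
20,0.02,0.1,20101130
20,0.05,0.15,20101130
20,0.1,0.3,20101130
20,0.166,0.4,20101130
20,0.25,0.65,20101130
20,0.35,0.95,20101130
20,0.5,1.5,20101130
20,0.75,1.5,20101130
20,1,1.8,20101130
20,1.3,1.8,20101130
30,0.02,0.1,20101130
30,0.05,0.15,20101130
30,0.1,0.25,20101130
30,0.166,0.35,20101130
30,0.25,0.5,20101130
30,0.35,0.75,20101130
30,0.5,1.15,20101130
30,0.75,1.5,20101130
30,1,1.8,20101130
30,1.3,1.8,20101130
45,0.02,0.05,20101130
45,0.05,0.1,20101130
45,0.1,0.2,20101130
45,0.166,0.3,20101130
45,0.25,0.45,20101130
45,0.35,0.6,20101130
45,0.5,0.9,20101130
45,0.75,1.5,20101130
45,1,1.8,20101130
45,1.3,1.8,20101130
65,0.02,0.05,20101130
65,0.05,0.1,20101130
65,0.1,0.2,20101130
65,0.166,0.3,20101130
65,0.25,0.4,20101130
65,0.35,0.55,20101130
65,0.5,0.75,20101130
65,0.75,1.35,20101130
65,1,1.8,20101130
65,1.3,1.8,20101130
90,0.02,0.05,20101130
90,0.05,0.1,20101130
90,0.1,0.15,20101130
90,0.166,0.25,20101130
90,0.25,0.35,20101130
90,0.35,0.5,20101130
90,0.5,0.75,20101130
90,0.75,1.2,20101130
90,1,1.8,20101130
90,1.3,1.8,20101130
120,0.02,0.05,20101130
120,0.05,0.1,20101130
120,0.1,0.15,20101130
120,0.166,0.25,20101130
120,0.25,0.35,20101130
120,0.35,0.45,20101130
120,0.5,0.7,20101130
120,0.75,1.1,20101130
120,1,1.8,20101130
120,1.3,1.8,20101130
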