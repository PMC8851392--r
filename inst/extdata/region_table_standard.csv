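region_id,name,hemisphere,lobe,homolog_id
1,temporal_01_L,L,temporal,31
2,temporal_02_L,L,temporal,32
3,occipital_01_L,L,occipital,33
4,occipital_02_L,L,occipital,34
5,occipital_03_L,L,occipital,35
6,temporal_03_L,L,temporal,36
7,temporal_04_L,L,temporal,37
8,temporal_05_L,L,temporal,38
9,PCG_01_L,L,PCG,39
10,parietal_01_L,L,parietal,40
11,temporal_06_L,L,temporal,41
12,temporal_07_L,L,temporal,42
13,temporal_08_L,L,temporal,43
14,parietal_02_L,L,parietal,44
15,parietal_03_L,L,parietal,45
16,temporal_09_L,L,temporal,46
17,temporal_10_L,L,temporal,47
18,frontal_01_L,L,frontal,48
19,frontal_02_L,L,frontal,49
20,frontal_03_L,L,frontal,50
21,frontal_04_L,L,frontal,51
22,frontal_05_L,L,frontal,52
23,frontal_06_L,L,frontal,53
24,frontal_07_L,L,frontal,54
25,frontal_08_L,L,frontal,55
26,frontal_09_L,L,frontal,56
27,frontal_10_L,L,frontal,57
28,frontal_11_L,L,frontal,58
29,frontal_12_L,L,frontal,59
30,frontal_13_L,L,frontal,60
31,temporal_01_R,R,temporal,1
32,temporal_02_R,R,temporal,2
33,occipital_01_R,R,occipital,3
34,occipital_02_R,R,occipital,4
35,occipital_03_R,R,occipital,5
36,temporal_03_R,R,temporal,6
37,temporal_04_R,R,temporal,7
38,temporal_05_R,R,temporal,8
39,PCG_01_R,R,PCG,9
40,parietal_01_R,R,parietal,10
41,temporal_06_R,R,temporal,11
42,temporal_07_R,R,temporal,12
43,temporal_08_R,R,temporal,13
44,parietal_02_R,R,parietal,14
45,parietal_03_R,R,parietal,15
46,temporal_09_R,R,temporal,16
47,temporal_10_R,R,temporal,17
48,frontal_01_R,R,frontal,18
49,frontal_02_R,R,frontal,19
50,frontal_03_R,R,frontal,20
51,frontal_04_R,R,frontal,21
52,frontal_05_R,R,frontal,22
53,frontal_06_R,R,frontal,23
54,frontal_07_R,R,frontal,24
55,frontal_08_R,R,frontal,25
56,frontal_09_R,R,frontal,26
57,frontal_10_R,R,frontal,27
58,frontal_11_R,R,frontal,28
59,frontal_12_R,R,frontal,29
60,frontal_13_R,R,frontal,30
61,cerebellum_L,L,cerebellum,62
62,cerebellum_R,R,cerebellum,61
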