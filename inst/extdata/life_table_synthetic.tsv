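age	qx
25	0.00078319395376891254
26	0.00080982180374422619
27	0.00083895185883131607
28	0.00087081916635378676
29	0.00090568083660680365
30	0.00094381811058419363
31	0.00098553862085204447
32	0.0010311788634884689
33	0.0010811069006404495
34	0.0011357253150334756
35	0.0011954744397093542
36	0.0012608358883690052
37	0.0013323364139937732
38	0.0014105521258988007
39	0.0014961130980705173
40	0.0015897084045658483
41	0.0016920916209119952
42	0.001804086833874341
43	0.0019265952056591873
44	0.0020606021426101684
45	0.0022071851227609685
46	0.0023675222412368191
47	0.0025429015374643926
48	0.0027347311734751134
49	0.0029445505382800219
50	0.0031740423593581424
51	0.0034250459087463714
52	0.0036995713980454425
53	0.0039998156638461069
54	0.0043281792526306262
55	0.004687285022072829
56	0.0050799983838105689
57	0.0055094493211357287
58	0.0059790563235520011
59	0.0064925523886826264
60	0.0070540132504202102
61	0.0076678880003266947
62	0.0083390322768597258
63	0.00907274420375348
64	0.009874803264440235
65	0.010751512303317501
66	0.011709742846404803
67	0.012756983932818655
68	0.013901394643716092
69	0.0151518605059483
70	0.016518053932439214
71	0.018010498838881062
72	0.019640639545034588
73	0.021420914026780036
74	0.023364831529757879
75	0.025487054484242599
76	0.027803484570639192
77	0.030331352671990719
78	0.033089312309911856
79	0.036097535988546037
80	0.039377813662010541
81	0.042953652288133748
82	0.046850375128263622
83	0.051095219091996658
84	0.055717427998738578
85	0.060748339126534989
86	0.066221459833844976
87	0.072172530363314058
88	0.078639568160238316
89	0.085662888155845884
90	0.093285092472728648
91	0.10155102190647336
92	0.11050766032904458
93	0.12020398185878334
94	0.13069072927262726
95	0.14202011073597987
96	0.15424540055047675
97	0.16742042834871551
98	0.18159894010564004
99	0.19683381363125385
100	0.21317611104248935
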