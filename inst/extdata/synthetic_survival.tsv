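age	survival
30	1
31	0.999465456481438
32	0.998883814710592
33	0.998250956246007
34	0.9975624083192
35	0.996813314428414
36	0.995998402694008
37	0.995111951843973
38	0.99414775469841
39	0.993099079024184
40	0.991958625636124
41	0.990718483629457
42	0.989370082640668
43	0.987904142051342
44	0.986310617072966
45	0.984578641681324
46	0.982696468408445
47	0.98065140504975
48	0.978429748406016
49	0.976016715256196
50	0.973396370850636
51	0.970551555327534
52	0.967463808591951
53	0.964113294359816
54	0.960478724263175
55	0.956537283141747
56	0.952264556914335
57	0.947634464736675
58	0.942619197515018
59	0.937189165262038
60	0.931312956258426
61	0.924957311523779
62	0.918087118707237
63	0.910665430183097
64	0.902653510878188
65	0.894010922161541
66	0.884695648983283
67	0.874664278343149
68	0.86387223807526
69	0.85227410582056
70	0.839823998873628
71	0.826476056272953
72	0.812185024969988
73	0.79690696205694
74	0.780600064725047
75	0.763225638704522
76	0.744749214215283
77	0.725141815715553
78	0.704381387729246
79	0.682454373500469
80	0.659357435898061
81	0.63509930062587
82	0.609702690185919
83	0.583206303085241
84	0.555666776517584
85	0.527160552455826
86	0.497785547335166
87	0.467662505268522
88	0.436935895488069
89	0.405774198501098
90	0.374369414957095
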