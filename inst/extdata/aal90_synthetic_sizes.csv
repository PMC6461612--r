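"region_id","name","abbreviation","hemisphere","homotopic_partner_id","size_volume","size_area"
1,"Precentral gyrus left","PreCG.L","L",2,11155,4123
2,"Precentral gyrus right","PreCG.R","R",1,11308,3813
3,"Superior frontal gyrus, dorsolateral left","SFGdor.L","L",4,15546,8748
4,"Superior frontal gyrus, dorsolateral right","SFGdor.R","R",3,15442,8699
5,"Superior frontal gyrus, orbital part left","ORBsup.L","L",6,2415,1962
6,"Superior frontal gyrus, orbital part right","ORBsup.R","R",5,2621,1761
7,"Middle frontal gyrus left","MFG.L","L",8,11927,2823
8,"Middle frontal gyrus right","MFG.R","R",7,12117,2812
9,"Middle frontal gyrus, orbital part left","ORBmid.L","L",10,29162,3117
10,"Middle frontal gyrus, orbital part right","ORBmid.R","R",9,29251,3092
11,"Inferior frontal gyrus, opercular part left","IFGoperc.L","L",12,8037,7164
12,"Inferior frontal gyrus, opercular part right","IFGoperc.R","R",11,8372,7256
13,"Inferior frontal gyrus, triangular part left","IFGtriang.L","L",14,15309,7004
14,"Inferior frontal gyrus, triangular part right","IFGtriang.R","R",13,15193,6965
15,"Inferior frontal gyrus, orbital part left","ORBinf.L","L",16,11961,3189
16,"Inferior frontal gyrus, orbital part right","ORBinf.R","R",15,12382,3122
17,"Rolandic operculum left","ROL.L","L",18,9551,3922
18,"Rolandic operculum right","ROL.R","R",17,9886,3977
19,"Supplementary motor area left","SMA.L","L",20,10361,1494
20,"Supplementary motor area right","SMA.R","R",19,10664,1548
21,"Olfactory cortex left","OLF.L","L",22,9650,5698
22,"Olfactory cortex right","OLF.R","R",21,9262,5736
23,"Superior frontal gyrus, medial left","SFGmed.L","L",24,4806,6845
24,"Superior frontal gyrus, medial right","SFGmed.R","R",23,4693,6802
25,"Superior frontal gyrus, medial orbital left","ORBsupmed.L","L",26,9903,5724
26,"Superior frontal gyrus, medial orbital right","ORBsupmed.R","R",25,10119,5534
27,"Gyrus rectus left","REC.L","L",28,11605,2565
28,"Gyrus rectus right","REC.R","R",27,11728,2582
29,"Insula left","INS.L","L",30,11786,9142
30,"Insula right","INS.R","R",29,12335,9149
31,"Anterior cingulate and paracingulate gyri left","ACG.L","L",32,15348,5648
32,"Anterior cingulate and paracingulate gyri right","ACG.R","R",31,15049,5688
33,"Median cingulate and paracingulate gyri left","DCG.L","L",34,9930,8897
34,"Median cingulate and paracingulate gyri right","DCG.R","R",33,9826,8865
35,"Posterior cingulate gyrus left","PCG.L","L",36,9763,3448
36,"Posterior cingulate gyrus right","PCG.R","R",35,9114,3280
37,"Hippocampus left","HIP.L","L",38,16346,1500
38,"Hippocampus right","HIP.R","R",37,16760,1503
39,"Parahippocampal gyrus left","PHG.L","L",40,9648,6847
40,"Parahippocampal gyrus right","PHG.R","R",39,9249,6731
41,"Amygdala left","AMYG.L","L",42,10263,10446
42,"Amygdala right","AMYG.R","R",41,10072,10508
43,"Calcarine fissure and surrounding cortex left","CAL.L","L",44,21234,4530
44,"Calcarine fissure and surrounding cortex right","CAL.R","R",43,21522,4520
45,"Cuneus left","CUN.L","L",46,12484,5267
46,"Cuneus right","CUN.R","R",45,12635,5035
47,"Lingual gyrus left","LING.L","L",48,4354,7177
48,"Lingual gyrus right","LING.R","R",47,4533,7088
49,"Superior occipital gyrus left","SOG.L","L",50,21549,3706
50,"Superior occipital gyrus right","SOG.R","R",49,21195,3548
51,"Middle occipital gyrus left","MOG.L","L",52,26227,3698
52,"Middle occipital gyrus right","MOG.R","R",51,26605,3735
53,"Inferior occipital gyrus left","IOG.L","L",54,11392,2298
54,"Inferior occipital gyrus right","IOG.R","R",53,11768,2416
55,"Fusiform gyrus left","FFG.L","L",56,14087,11443
56,"Fusiform gyrus right","FFG.R","R",55,14314,11267
57,"Postcentral gyrus left","PoCG.L","L",58,6216,3404
58,"Postcentral gyrus right","PoCG.R","R",57,6476,3457
59,"Superior parietal gyrus left","SPG.L","L",60,29254,3033
60,"Superior parietal gyrus right","SPG.R","R",59,29433,2907
61,"Inferior parietal lobule left","IPL.L","L",62,8956,11074
62,"Inferior parietal lobule right","IPL.R","R",61,8296,11129
63,"Supramarginal gyrus left","SMG.L","L",64,9173,6075
64,"Supramarginal gyrus right","SMG.R","R",63,8935,6098
65,"Angular gyrus left","ANG.L","L",66,28255,3235
66,"Angular gyrus right","ANG.R","R",65,28069,3379
67,"Precuneus left","PCUN.L","L",68,27186,2214
68,"Precuneus right","PCUN.R","R",67,26836,2271
69,"Paracentral lobule left","PCL.L","L",70,13500,7778
70,"Paracentral lobule right","PCL.R","R",69,13476,7892
71,"Caudate nucleus left","CAU.L","L",72,21892,4300
72,"Caudate nucleus right","CAU.R","R",71,22372,4302
73,"Lenticular nucleus, putamen left","PUT.L","L",74,14004,8606
74,"Lenticular nucleus, putamen right","PUT.R","R",73,14635,8614
75,"Lenticular nucleus, pallidum left","PAL.L","L",76,5829,4271
76,"Lenticular nucleus, pallidum right","PAL.R","R",75,5160,4336
77,"Thalamus left","THA.L","L",78,13141,4282
78,"Thalamus right","THA.R","R",77,12864,4365
79,"Heschl gyrus left","HES.L","L",80,12426,1504
80,"Heschl gyrus right","HES.R","R",79,11817,1572
81,"Superior temporal gyrus left","STG.L","L",82,6306,1693
82,"Superior temporal gyrus right","STG.R","R",81,6437,1522
83,"Temporal pole: superior temporal gyrus left","TPOsup.L","L",84,7248,3743
84,"Temporal pole: superior temporal gyrus right","TPOsup.R","R",83,6889,3736
85,"Middle temporal gyrus left","MTG.L","L",86,48281,2743
86,"Middle temporal gyrus right","MTG.R","R",85,48213,2918
87,"Temporal pole: middle temporal gyrus left","TPOmid.L","L",88,10025,3014
88,"Temporal pole: middle temporal gyrus right","TPOmid.R","R",87,10046,3062
89,"Inferior temporal gyrus left","ITG.L","L",90,11422,2315
90,"Inferior temporal gyrus right","ITG.R","R",89,11018,2298
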