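stratum,case,meth1,meth2,meth3,meth4,expr1,expr2
1,1,1.371,0.206,1.5127,-1.4936,-0.1755,-2.0009
1,0,-0.5647,-0.3611,0.2579,-1.4704,-1.0718,0.3338
2,1,0.3631,0.7582,0.0884,0.1247,0.1632,1.1713
2,0,0.6329,-0.7267,-0.1209,-0.9966,-0.3627,2.0595
3,0,0.4043,-1.3683,-1.1943,-0.0018,0.59,-1.3769
3,1,-0.1061,0.4328,0.612,-0.4283,1.4324,-1.1509
4,0,1.5115,-0.8114,-0.2171,-0.6137,-0.9927,-0.7058
4,1,-0.0947,1.4441,-0.1828,-2.0247,0.4547,-1.0541
5,0,2.0184,-0.4314,0.9333,-1.2247,0.0849,-0.6457
5,1,-0.0627,0.6556,0.8218,0.1795,0.8956,-0.1854
6,1,1.3049,0.3219,1.3921,0.5676,-0.2298,-1.2012
6,0,2.2866,-0.7838,-0.4762,-0.4929,0.8366,2.037
7,1,-1.3889,1.5757,0.6503,1e-04,-1.7451,0.1078
7,0,-0.2788,0.6429,1.3911,1.1229,1.6895,-0.0841
8,0,-0.1333,0.0898,-1.1108,1.4399,0.8648,0.4956
8,1,0.636,0.2766,-0.8608,-1.0971,-0.1508,0.0374
9,1,-0.2843,0.6793,-1.1317,-0.1173,-1.449,-0.1321
9,0,-2.6565,0.0898,-1.4592,1.2015,0.643,1.4768
10,0,-2.4405,-2.9931,0.08,-0.4697,0.4832,-0.217
10,1,1.3201,0.2849,0.6532,-0.0525,-0.0064,-1.2836
11,0,-0.3066,-0.3672,1.201,-0.0861,0.1515,0.3857
11,1,-1.7813,0.1852,1.0448,-0.8877,-0.5841,-0.3515
12,0,-0.1719,0.5818,-1.0032,-0.4447,0.3688,-0.5218
12,1,1.2147,1.3997,1.8485,-0.0294,0.2947,-1.0681
13,0,1.8952,-0.7273,-0.6668,-0.4139,-0.2793,0.4284
13,1,-0.4305,1.3025,0.1055,1.1134,-1.3362,-0.174
14,1,-0.2573,0.3358,-0.4223,-0.481,0.7007,0.5157
14,0,-1.7632,1.0385,-0.1224,-0.4332,0.5542,-0.2344
15,1,0.4601,0.9207,0.1882,0.6969,-0.8363,-0.6585
15,0,-0.64,0.7209,0.1192,-1.0564,-1.5946,1.2502
16,0,0.4555,-1.0431,-0.0251,-0.0407,0.205,-0.2718
16,1,0.7048,-0.0902,0.1081,-1.5515,-0.3451,0.948
17,1,1.0351,0.6235,-0.4854,1.1672,0.2526,-1.2016
17,0,-0.6089,-0.9535,-0.5042,-0.2736,-1.294,-0.4661
18,1,0.505,-0.5428,-1.6611,-0.4678,-0.9592,-0.2694
18,0,-1.717,0.581,-0.3823,-1.2383,1.0858,-0.391
19,1,-0.7845,0.7682,-0.5127,-0.0078,0.4038,1.3487
19,0,-0.8509,0.4638,2.7019,-0.8003,0.5865,-0.0228
20,0,-2.4142,-0.8858,-1.3621,-0.5335,1.8152,0.2442
20,1,0.0361,-1.0998,0.1373,1.2877,0.1288,-0.9424
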