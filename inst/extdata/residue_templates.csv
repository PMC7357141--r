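resname,atom,element,x,y,z
A,OP3,O,8.4121,-1.7359,-3.2771
A,P,P,8.1246,-1.3492,-1.7414
A,OP1,O,7.8784,-2.5806,-0.9602
A,OP2,O,9.3996,-0.5753,-1.1368
A,O5',O,6.8305,-0.3950,-1.6605
A,C5',C,6.6278,-0.0879,-0.2814
A,C4',C,5.4054,0.8194,-0.1335
A,O4',O,4.2204,0.1501,-0.6157
A,C3',C,5.1195,1.1044,1.3569
A,O3',O,5.6594,2.3705,1.7387
A,C2',C,3.5769,1.1235,1.4469
A,O2',O,3.1160,2.4018,1.8889
A,C1',C,3.1147,0.8443,-0.0003
A,N9,N,1.9185,0.0000,-0.0007
A,C8,C,1.8935,-1.3626,-0.0009
A,N7,N,0.6627,-1.7847,-0.0010
A,C5,C,-0.1783,-0.7236,0.0051
A,C6,C,-1.5750,-0.5688,-0.0018
A,N6,N,-2.4091,-1.6731,-0.0027
A,N1,N,-2.0763,0.6613,-0.0009
A,C2,C,-1.2874,1.7196,-0.0001
A,N3,N,0.0251,1.6240,0.0001
A,C4,C,0.6172,0.4348,0.0001
A,HOP3,H,9.1924,-2.3063,-3.2799
A,HOP2,H,9.5247,0.2190,-1.6720
A,H5',H,7.5084,0.4213,0.1107
A,H5'',H,6.4640,-1.0105,0.2758
A,H4',H,5.5612,1.7537,-0.6744
A,H3',H,5.5296,0.3115,1.9821
A,HO3',H,5.4511,2.4927,2.6748
A,H2',H,3.2230,0.3386,2.1159
A,HO2',H,3.4860,2.5420,2.7715
A,H1',H,2.9166,1.7810,-0.5212
A,H8,H,2.7668,-1.9980,-0.0008
A,H61,H,-3.3712,-1.5534,-0.0025
A,H62,H,-2.0316,-2.5664,-0.0064
A,H2,H,-1.7370,2.7019,-0.0002
C,OP3,O,5.6147,-2.8737,-5.4267
C,P,P,5.6010,-3.2255,-3.8556
C,OP1,O,4.6783,-4.3550,-3.6103
C,OP2,O,7.0862,-3.6323,-3.3857
C,O5',O,5.1086,-1.9393,-3.0219
C,C5',C,5.1180,-2.3118,-1.6439
C,C4',C,4.6568,-1.1291,-0.7913
C,O4',O,3.3056,-0.7551,-1.1395
C,C3',C,4.5845,-1.5302,0.6984
C,O3',O,5.7621,-1.1067,1.3886
C,C2',C,3.3423,-0.7781,1.2307
C,O2',O,3.7147,0.1298,2.2692
C,C1',C,2.8114,-0.0148,-0.0023
C,N1,N,1.3465,-0.0000,-0.0005
C,C2,C,0.6665,-1.1594,-0.0009
C,O2,O,1.2785,-2.2148,-0.0026
C,N3,N,-0.6658,-1.1759,0.0004
C,C4,C,-1.3562,-0.0434,0.0016
C,N4,N,-2.7311,-0.0715,0.0024
C,C5,C,-0.6724,1.1896,-0.0029
C,C6,C,0.6813,1.1890,0.0024
C,HOP3,H,5.9149,-3.6683,-5.8887
C,HOP2,H,7.6537,-2.8715,-3.5617
C,H5',H,6.1281,-2.5975,-1.3524
C,H5'',H,4.4429,-3.1546,-1.4905
C,H4',H,5.3297,-0.2822,-0.9231
C,H3',H,4.4513,-2.6078,0.7964
C,HO3',H,5.6604,-1.3839,2.3099
C,H2',H,2.5949,-1.4833,1.5923
C,HO2',H,4.0938,-0.4007,2.9825
C,H1',H,3.2002,1.0032,-0.0141
C,H41,H,-3.1989,-0.9210,0.0016
C,H42,H,-3.2337,0.7573,0.0077
C,H5,H,-1.2209,2.1199,-0.0015
C,H6,H,1.2273,2.1209,0.0019
G,OP3,O,8.4193,1.7091,3.2705
G,P,P,8.1296,1.3225,1.7350
G,OP1,O,7.8891,2.5544,0.9535
G,OP2,O,9.4012,0.5430,1.1291
G,O5',O,6.8315,0.3743,1.6562
G,C5',C,6.6260,0.0675,0.2770
G,C4',C,5.4005,-0.8347,0.1299
G,O4',O,4.2186,-0.1598,0.6129
G,C3',C,5.1120,-1.1185,-1.3593
G,O3',O,5.6464,-2.3879,-1.7412
G,C2',C,3.5682,-1.1307,-1.4489
G,O2',O,3.1023,-2.4074,-1.8898
G,C1',C,3.1095,-0.8493,-0.0017
G,N9,N,1.9162,0.0000,-0.0006
G,C8,C,1.8986,1.3644,-0.0006
G,N7,N,0.6688,1.7899,0.0002
G,C5,C,-0.1730,0.7271,0.0007
G,C6,C,-1.5803,0.5857,0.0022
G,O6,O,-2.3062,1.5653,0.0032
G,N1,N,-2.0993,-0.6613,-0.0039
G,C2,C,-1.2779,-1.7480,0.0018
G,N2,N,-1.8338,-3.0029,0.0026
G,N3,N,0.0305,-1.6303,0.0005
G,C4,C,0.6164,-0.4276,-0.0002
G,HOP3,H,9.2031,2.2758,3.2729
G,HOP2,H,9.5235,-0.2524,1.6661
G,H5',H,7.5048,-0.4460,-0.1156
G,H5'',H,6.4669,0.9904,-0.2810
G,H4',H,5.5509,-1.7695,0.6718
G,H3',H,5.5257,-0.3280,-1.9854
G,HO3',H,5.4370,-2.5099,-2.6769
G,H2',H,3.2179,-0.3450,-2.1185
G,HO2',H,3.4718,-2.5500,-2.7730
G,H1',H,2.9071,-1.7849,0.5206
G,H8,H,2.7736,1.9974,-0.0008
G,H1,H,-3.0620,-0.7834,-0.0032
G,H21,H,-1.2619,-3.7869,0.0012
G,H22,H,-2.7981,-3.1060,0.0068
U,OP3,O,5.6463,3.0072,5.3306
U,P,P,5.6320,3.3121,3.7501
U,OP1,O,4.7157,4.4401,3.4732
U,OP2,O,7.1186,3.6969,3.2664
U,O5',O,5.1302,2.0054,2.9549
U,C5',C,5.1400,2.3373,1.5666
U,C4',C,4.6710,1.1320,0.7505
U,O4',O,3.3164,0.7767,1.1109
U,C3',C,4.5971,1.4850,-0.7512
U,O3',O,5.7680,1.0288,-1.4314
U,C2',C,3.3489,0.7298,-1.2568
U,O2',O,3.7099,-0.2135,-2.2684
U,C1',C,2.8147,0.0050,-0.0022
U,N1,N,1.3492,-0.0000,-0.0016
U,C2,C,0.6797,1.1647,0.0027
U,O2,O,1.2969,2.2113,0.0012
U,N3,N,-0.6669,1.1885,-0.0019
U,C4,C,-1.3666,0.0358,0.0002
U,O4,O,-2.5845,0.0569,0.0013
U,C5,C,-0.6729,-1.1970,0.0009
U,C6,C,0.6775,-1.1920,-0.0002
U,HOP3,H,5.9513,3.8137,5.7689
U,HOP2,H,7.6822,2.9373,3.4641
U,H5',H,6.1524,2.6081,1.2654
U,H5'',H,4.4709,3.1785,1.3891
U,H4',H,5.3402,0.2851,0.9059
U,H3',H,4.4734,2.5599,-0.8850
U,HO3',H,5.6527,1.2498,-2.3664
U,H2',H,2.6063,1.4300,-1.6388
U,HO2',H,4.0920,0.2912,-2.9982
U,H1',H,3.1973,-1.0139,0.0397
U,H3,H,-1.1348,2.0385,-0.0020
U,H5,H,-1.2169,-2.1301,0.0021
U,H6,H,1.2230,-2.1230,0.0007
ARG,N,N,1.8500,5.8655,-0.1985
ARG,CA,C,0.9573,5.5411,-1.3096
ARG,C,C,-0.1926,6.5322,-1.2971
ARG,O,O,-0.3740,7.3994,-0.4523
ARG,CB,C,0.4647,4.0880,-1.2319
ARG,CG,C,-0.3978,3.7714,0.0004
ARG,CD,C,-0.9085,2.3321,-0.0003
ARG,NE,N,0.1884,1.3936,-0.0000
ARG,CZ,C,0.0038,0.0000,0.0000
ARG,NH1,N,1.0914,-0.8664,-0.0000
ARG,NH2,N,-1.2836,-0.5272,-0.0000
ARG,OXT,O,-1.0276,6.3545,-2.3558
ARG,H,H,2.7244,5.3901,-0.1477
ARG,H2,H,1.4766,6.3851,0.5648
ARG,HA,H,1.5194,5.6885,-2.2393
ARG,HB2,H,1.3330,3.4171,-1.2438
ARG,HB3,H,-0.1126,3.8603,-2.1378
ARG,HG2,H,-1.2670,4.4397,0.0213
ARG,HG3,H,0.1746,3.9572,0.9172
ARG,HD2,H,-1.5150,2.1592,0.8954
ARG,HD3,H,-1.5481,2.1499,-0.8705
ARG,HE,H,1.1593,1.7283,0.0028
ARG,HH11,H,0.9562,-1.8751,-0.0006
ARG,HH12,H,2.0495,-0.5269,0.0030
ARG,HH21,H,-2.1006,0.0780,-0.0009
ARG,HH22,H,-1.4410,-1.5323,-0.0014
ARG,HXT,H,-1.7888,6.9724,-2.3973
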