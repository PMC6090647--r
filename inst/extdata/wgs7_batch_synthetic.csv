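time_h,X_gL,S_gL,PA_gL,PYR_gL,AA_gL,SA_gL
0,0.0697652480664955,84.580417679586,0,0,0,0
4,0.263307915521111,77.6536501418517,0.272890724450216,0,0.227520205690138,0
8,0.820346800719742,74.072730851313,1.03149922180459,0,1.00498877098389,0
12,2.26252167473847,71.432693583858,2.70284437200408,0.111700130304102,2.45957954145089,0.0692346438841084
16,3.81165012561394,64.6366234318346,5.45087550811031,0.167578978750884,4.90398884636601,0.188389564011337
20,6.55018430825717,59.8264811286331,8.58215299313079,0.134192558533118,8.12281710268263,0.406751310810825
24,8.85078171211207,47.3965767188484,12.7871315274498,0.109704611858367,10.4377992833323,0.684695714549087
28,9.55275170564616,36.8799267705026,15.6245992705946,0.0886301269210584,13.1780870677575,0.97299959234268
32,11.4147179579828,27.8832721862024,19.606278758248,0.0662589334428562,13.9356420950579,1.49046718883866
36,14.0710912744264,19.2526436044016,25.6980303758098,0.062657572758868,16.8796391349508,1.91113469522285
40,14.084821152372,11.4119878615681,29.6656211978764,0.0555770454436545,20.3965151712535,2.47853796967047
44,14.4105341978104,4.45550128709724,33.8654629246428,0,18.5505319486444,2.86011641061464
48,15.6702501735512,0.693520219099614,32.1205502336035,0,18.156739393974,3.37486621465776
52,15.1595080753306,0,38.6049032690524,0,18.8049754492759,3.81492261795798
56,13.5290262258631,0,41.4476795156098,0,16.9245190538365,4.21477501700517
60,12.2577378354777,0,37.9955806992039,0,16.6432203166424,4.88553490057931
64,10.353725082563,0,38.1614437014005,0,16.0195587317713,5.24848507757731
68,11.098685373212,0,40.7482405303444,0,15.4494915590965,5.46014251401986
72,9.10078475979895,0,39.9666243816373,0,13.2228900717272,5.92767631168967
76,9.2060468385004,0,41.4590468825249,0,12.3126770554956,6.74108841089661
80,7.83076139188895,0,41.3853150063525,0,12.4035193332292,6.38311800097525
84,7.67426471127382,0,41.7574431494375,0,10.6043315555847,6.86755427934789
88,6.92618407413072,0,49.503794705606,0,9.89971495974781,7.15938561690951
92,6.69025437073631,0,48.0508866176228,0,9.34043363144378,6.81612803475203
96,6.25223443236449,0,47.1141670464607,0,8.83259816321286,7.54889924938086
100,5.87337612588809,0,48.9065127297747,0,8.84576384155172,7.67040991037692
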