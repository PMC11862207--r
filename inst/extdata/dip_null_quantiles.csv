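n,0.010,0.020,0.050,0.100,0.200,0.300,0.400,0.500,0.600,0.700,0.800,0.900,0.950,0.975,0.990,0.995,0.999
30,0.0396616442677116,0.0415497326802063,0.0444481367327308,0.0474279935781204,0.0516315385112636,0.055103254917736,0.0582576223624546,0.0614657117295009,0.0649370595214916,0.069046274238285,0.073985306665843,0.0815466273038423,0.0881679529294677,0.0941737465083671,0.101668675239457,0.10693238978858,0.118285536561211
40,0.0347638311767544,0.0362705556198453,0.0390851633496799,0.0418548820875789,0.0455205809056585,0.0485138710035088,0.0512950128097079,0.0541511970725471,0.057271111978693,0.0607678265643027,0.0651290552827845,0.0717854908849863,0.0777408343496191,0.0831710123861519,0.0894969653057601,0.0939723878314206,0.102367830798671
50,0.0313761311429666,0.0328503856884171,0.035323209165642,0.0377573680252805,0.041123086120113,0.0437940578807929,0.0463006588035836,0.0488681921736169,0.0516725852610614,0.0548323302475088,0.0587878441298421,0.0648961578896004,0.0702195634309455,0.0751611830401242,0.080750260543439,0.0846740353862958,0.0932432562275117
65,0.0278787206957712,0.029113790421394,0.0313242717703304,0.0334921224266637,0.0363916919264395,0.0387747251218041,0.0410194603399568,0.0432889712169538,0.04572719714175,0.0484749369703645,0.0520167541920449,0.0573844351265349,0.0620812149091426,0.0662422168038971,0.0715288316695726,0.0753589238008975,0.0837504323625745
80,0.025337277127145,0.0265278040433764,0.0284505603013703,0.0304088883507379,0.0331224908847059,0.0352734868512862,0.0373291586603246,0.0393576727569104,0.0415926478641765,0.0441516121934271,0.0473859243152289,0.052255060970568,0.0567143401275109,0.0609014052144468,0.0660166217646474,0.069549120889161,0.0758926238969954
100,0.022792742202017,0.0238960629218721,0.0255902381410245,0.0273234849911126,0.0297934385811189,0.0317209883388081,0.0335812937014545,0.0354282859840296,0.0374574450786451,0.0397837438968424,0.0426772243634317,0.0470578662182742,0.0510142686874198,0.0545454888232749,0.0587205351012648,0.0619564775590524,0.0682870585290116
130,0.0202672046219801,0.021155456609784,0.0226756552830685,0.024242192422605,0.0264069342499627,0.0281155365382008,0.0297115638257232,0.0313503971424107,0.0331504463043121,0.0352196613724447,0.0378303125859045,0.0417349026014642,0.045282257232158,0.0485654832065932,0.0523069327548604,0.0545827489380398,0.0604076419513055
160,0.0183377921294458,0.0191655647353978,0.0205939249314036,0.0219991811571443,0.0239151978564879,0.025485655812528,0.02693807404088,0.0284290373022595,0.0300448384681158,0.0318986666241413,0.0342297138582774,0.0377301333321288,0.0409076313961396,0.0437894395760561,0.0472123342264498,0.0497281298491226,0.0548755484540414
200,0.0165321372602933,0.0172841384911864,0.0185659972529276,0.0197915727740211,0.0214926933066367,0.0229039709283321,0.0242247069147421,0.0255504720787307,0.0269859168829306,0.0286795679083862,0.0307959049160596,0.0340566863111946,0.0369380635862672,0.0395846324214522,0.0429555644819574,0.0452148209849089,0.0496436875088843
250,0.0148322671760575,0.0155598938094963,0.0166501124331317,0.0177818995115108,0.0193258307021568,0.0206005970332477,0.0217916670170243,0.0229828825741098,0.0242840651762247,0.0257744582107322,0.0276242053142243,0.0304539779113537,0.0329749878812493,0.0352752897882782,0.0381024901440303,0.0401534566527568,0.0443390330896506
300,0.0136547253958986,0.0142476410726607,0.0152661534392437,0.0163221555594162,0.0177210960587274,0.0188676751623403,0.0199361505341037,0.0210475356134637,0.0222421871829263,0.0236229279149937,0.0253406776572237,0.0279493711515366,0.0303184385558766,0.0324878522098792,0.0352243992695181,0.0370013438041213,0.0412850636762046
400,0.011901278574872,0.0124221245928782,0.0133056961721073,0.0141979672130821,0.015427580935433,0.0164412422850246,0.017366409643031,0.01830410872921,0.0193155648779369,0.0205305727389172,0.0220556083548164,0.0243446705386744,0.0264342233339286,0.0283153135830301,0.0305955486422265,0.0322192807564473,0.0354781240420592
500,0.0106423147319074,0.0111681102609578,0.0119459950130019,0.012763005840941,0.0138658705567714,0.0147670477393675,0.0156219937809678,0.0164793107760612,0.0174089326311483,0.0184691496780732,0.0198131574632156,0.0218717300116788,0.0237270790834395,0.0254053810633016,0.0274625261558121,0.0289538164295674,0.0319501100251359
700,0.00901513889804927,0.00942502218289224,0.0100905361121065,0.0107758568159513,0.0117365061890837,0.012518055882591,0.0132433328829519,0.0139608222252498,0.0147522878372818,0.0156740454299865,0.0168228550614484,0.018561381063254,0.0201230582580459,0.0215446307979429,0.0232588486680548,0.0243188745749384,0.0271605822699576
1000,0.00758743488508868,0.00792848547263682,0.00851178194256326,0.00910125399969176,0.00988357019165421,0.0105226863143252,0.0111111610506971,0.0117203204997587,0.0123886053284146,0.0131481421245735,0.0141335067304758,0.0155720725702179,0.0168510651314432,0.0180367555958061,0.0195285046915711,0.0205810781074094,0.0225596322775351
1500,0.00620707504290259,0.00650119640737689,0.00699332611105175,0.00747158910373453,0.00810601890700207,0.00864004555303508,0.00911927763894295,0.0096192209130502,0.0101466524775681,0.0107659843336948,0.0115622882997913,0.0127794134870263,0.0138239220630331,0.0148485637339775,0.0160354335580724,0.0168723771478803,0.0185016396280941
2000,0.00540129315861463,0.00565390021128596,0.00607501335131674,0.0064774005085343,0.0070343400368946,0.00748653545595056,0.00792319984898693,0.00835166864323349,0.00882762926822852,0.00935978273899457,0.0100498449448421,0.0111124781036361,0.0120427526401047,0.0129338817304794,0.0139919915008827,0.0147005624771979,0.0162024980929519
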