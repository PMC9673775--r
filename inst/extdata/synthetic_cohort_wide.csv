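subject_id,11,12,13,21,22,23,31,32,33,41,42,43
S0001,7.905414355266148,6.8074318822266005,7.884482551482409,7.923802759798948,6.764053005236189,7.921144520808136,5.0109679756422825,6.045080007369263,6.212492006768304,5.476097735428674,5.97448658008161,5.666752751079424
S0002,8.80491249930088,6.672783748848568,8.291336767632703,8.68492309809225,6.448849555079764,8.40108625228914,5.623181139039891,5.959793784801289,7.166555681480383,5.728277232273833,5.841373681050181,6.90925376078004
S0003,8.753483011334904,6.7436234833932005,7.9072513479725925,8.598062364583948,6.847855157268263,7.989347817108083,5.249935237189198,6.119691249963056,7.291016580574802,5.698587953289767,5.603783023139421,7.309665958553757
S0004,7.761667853716447,7.576135196276662,7.220641662627089,7.8153464933334815,7.185542410574375,7.238444638400857,5.373504311086191,6.2078357987164745,6.8555337051981615,5.280134852814052,6.346800110568882,6.758042801161446
S0005,8.493470172374629,7.062972036979603,8.429974002133994,8.628002059773605,7.10730230563834,8.22392844608487,5.335420940078944,6.385702076090841,7.580237365719633,5.276950651316474,6.434541201329645,7.465806534674756
S0006,8.517034656645146,7.277174012489541,8.288256776874661,8.84898483300107,7.132452862386297,8.413877679970023,5.573948582635419,6.439732184964456,6.947944120052243,5.513761332622902,6.420997770095395,6.725486549761034
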