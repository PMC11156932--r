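polarity,bin_center,mean_anomaly,sd,n,ci_halfwidth,ci_flag
AE,25,0.18813923,,1,,TRUE
AE,35,0.1881386569,,1,,TRUE
AE,45,0.1881394995,,1,,TRUE
AE,55,0.1881390522,,1,,TRUE
AE,65,0.1881390522,,1,,TRUE
AE,75,0.1881394995,,1,,TRUE
AE,85,0.1881386569,,1,,TRUE
AE,95,0.18813923,,1,,TRUE
AE,105,0.1881379342,,1,,TRUE
AE,115,0.1881389754,,1,,TRUE
AE,125,0.1881400423,,1,,TRUE
AE,135,0.188139855,,1,,TRUE
AE,145,0.1881388289,,1,,TRUE
AE,155,0.188139937,,1,,TRUE
AE,165,0.1881399717,,1,,TRUE
AE,175,0.1881407376,,1,,TRUE
AE,185,0.1881390228,,1,,TRUE
AE,195,0.1881405839,,1,,TRUE
AE,205,0.1881381827,,1,,TRUE
AE,215,0.1881386124,,1,,TRUE
AE,225,0.1881368167,,1,,TRUE
AE,235,0.188141123,,1,,TRUE
AE,245,0.1881402376,,1,,TRUE
AE,255,0.1881390895,,1,,TRUE
AE,265,0.1881390927,,1,,TRUE
AE,275,0.1881401372,,1,,TRUE
AE,285,0.1881401862,,1,,TRUE
AE,295,0.1881403004,,1,,TRUE
AE,305,0.1881360935,,1,,TRUE
AE,315,0.1881397088,,1,,TRUE
AE,325,0.188140483,,1,,TRUE
AE,335,0.1881409171,,1,,TRUE
AE,345,0.1881397145,,1,,TRUE
AE,355,0.1881378799,,1,,TRUE
AE,365,0.1881400808,,1,,TRUE
AE,375,0.1881387135,,1,,TRUE
AE,385,0.1881391024,,1,,TRUE
AE,395,0.1881383385,,1,,TRUE
AE,405,0.1881401307,,1,,TRUE
AE,415,0.1881387429,,1,,TRUE
AE,425,0.1881400487,,1,,TRUE
AE,435,0.1881371385,,1,,TRUE
AE,445,0.188142954,,1,,TRUE
AE,455,0.1881403951,,1,,TRUE
AE,465,0.1881388242,,1,,TRUE
AE,475,0.1881387922,,1,,TRUE
AE,485,0.1881376346,,1,,TRUE
AE,495,0.1881381004,,1,,TRUE
AE,505,0.1881381004,,1,,TRUE
AE,515,0.1881376346,,1,,TRUE
AE,525,0.1881387922,,1,,TRUE
AE,535,0.1881388242,,1,,TRUE
AE,545,0.1881403951,,1,,TRUE
AE,555,0.188142954,,1,,TRUE
AE,565,0.1881371385,,1,,TRUE
AE,575,0.1881400487,,1,,TRUE
AE,585,0.1881387429,,1,,TRUE
AE,595,0.1881401307,,1,,TRUE
AE,605,0.1881383385,,1,,TRUE
AE,615,0.1881391024,,1,,TRUE
AE,625,0.1881387135,,1,,TRUE
AE,635,0.1881400808,,1,,TRUE
AE,645,0.1881378799,,1,,TRUE
AE,655,0.1881397145,,1,,TRUE
AE,665,0.1881409171,,1,,TRUE
AE,675,0.188140483,,1,,TRUE
AE,685,0.1881397088,,1,,TRUE
AE,695,0.1881360935,,1,,TRUE
AE,705,0.1881397144,,1,,TRUE
AE,715,0.1881382801,,1,,TRUE
AE,725,0.1881388848,,1,,TRUE
AE,735,0.1881390957,,1,,TRUE
AE,745,0.1881397783,,1,,TRUE
CE,25,-0.1191870205,0.03319972162,2,0.04601246665,FALSE
CE,35,-0.1191888805,0.03320274405,2,0.04601665552,FALSE
CE,45,-0.1191877162,0.03320099897,2,0.04601423697,FALSE
CE,55,-0.1191872433,0.03320161063,2,0.04601508468,FALSE
CE,65,-0.1191872433,0.03320161063,2,0.04601508468,FALSE
CE,75,-0.1191877162,0.03320099897,2,0.04601423697,FALSE
CE,85,-0.1191888805,0.03320274405,2,0.04601665552,FALSE
CE,95,-0.1191870205,0.03319972162,2,0.04601246665,FALSE
CE,105,-0.1191870512,0.03320129408,2,0.04601464597,FALSE
CE,115,-0.119187648,0.03320059331,2,0.04601367475,FALSE
CE,125,-0.1191869896,0.03320189978,2,0.04601548542,FALSE
CE,135,-0.1191873406,0.03320279316,2,0.04601672359,FALSE
CE,145,-0.11918766,0.03319992443,2,0.04601274772,FALSE
CE,155,-0.1191874205,0.03320172735,2,0.04601524645,FALSE
CE,165,-0.1191870852,0.03320196626,2,0.04601557757,FALSE
CE,175,-0.1191876683,0.03320234884,2,0.04601610779,FALSE
CE,185,-0.1191874536,0.03320088152,2,0.04601407419,FALSE
CE,195,-0.1191867626,0.033203255,2,0.04601736366,FALSE
CE,205,-0.1191874809,0.03320178057,2,0.0460153202,FALSE
CE,215,-0.1191875977,0.03320427626,2,0.04601877906,FALSE
CE,225,-0.1191874431,0.03320153353,2,0.04601497783,FALSE
CE,235,-0.1191860525,0.03320009344,2,0.04601298197,FALSE
CE,245,-0.1191872818,0.03320066084,2,0.04601376834,FALSE
CE,255,-0.1191876792,0.03320149109,2,0.04601491902,FALSE
CE,265,-0.1191880157,0.0332011166,2,0.04601439999,FALSE
CE,275,-0.1191876389,0.03320143203,2,0.04601483716,FALSE
CE,285,-0.1191873321,0.0332031642,2,0.04601723782,FALSE
CE,295,-0.119187389,0.03320240622,2,0.04601618731,FALSE
CE,305,-0.1191879253,0.03320184088,2,0.0460154038,FALSE
CE,315,-0.1191888554,0.03319942956,2,0.04601206188,FALSE
CE,325,-0.1191872685,0.03320140343,2,0.04601479751,FALSE
CE,335,-0.1191869785,0.03320225461,2,0.04601597719,FALSE
CE,345,-0.1191866561,0.0332021098,2,0.0460157765,FALSE
CE,355,-0.1191874405,0.03320165019,2,0.04601513951,FALSE
CE,365,-0.1191866723,0.03320119153,2,0.04601450384,FALSE
CE,375,-0.119187286,0.03320227542,2,0.04601600604,FALSE
CE,385,-0.1191870562,0.03320147201,2,0.04601489256,FALSE
CE,395,-0.1191873906,0.03320234022,2,0.04601609584,FALSE
CE,405,-0.119187232,0.0332026173,2,0.04601647986,FALSE
CE,415,-0.1191884021,0.0332007018,2,0.04601382511,FALSE
CE,425,-0.1191870411,0.03320135747,2,0.04601473382,FALSE
CE,435,-0.1191869159,0.03320041179,2,0.04601342318,FALSE
CE,445,-0.1191864385,0.03320138485,2,0.04601477177,FALSE
CE,455,-0.1191859567,0.03319964258,2,0.04601235711,FALSE
CE,465,-0.1191875407,0.03320223465,2,0.04601594954,FALSE
CE,475,-0.1191867562,0.03320265712,2,0.04601653505,FALSE
CE,485,-0.1191871086,0.03320225445,2,0.04601597697,FALSE
CE,495,-0.1191872349,0.03320173683,2,0.04601525958,FALSE
CE,505,-0.1191872349,0.03320173683,2,0.04601525958,FALSE
CE,515,-0.1191871086,0.03320225445,2,0.04601597697,FALSE
CE,525,-0.1191867562,0.03320265712,2,0.04601653505,FALSE
CE,535,-0.1191875407,0.03320223465,2,0.04601594954,FALSE
CE,545,-0.1191859567,0.03319964258,2,0.04601235711,FALSE
CE,555,-0.1191864385,0.03320138485,2,0.04601477177,FALSE
CE,565,-0.1191869159,0.03320041179,2,0.04601342318,FALSE
CE,575,-0.1191870411,0.03320135747,2,0.04601473382,FALSE
CE,585,-0.1191884021,0.0332007018,2,0.04601382511,FALSE
CE,595,-0.119187232,0.0332026173,2,0.04601647986,FALSE
CE,605,-0.1191873906,0.03320234022,2,0.04601609584,FALSE
CE,615,-0.1191870562,0.03320147201,2,0.04601489256,FALSE
CE,625,-0.119187286,0.03320227542,2,0.04601600604,FALSE
CE,635,-0.1191866723,0.03320119153,2,0.04601450384,FALSE
CE,645,-0.1191874405,0.03320165019,2,0.04601513951,FALSE
CE,655,-0.1191866561,0.0332021098,2,0.0460157765,FALSE
CE,665,-0.1191869785,0.03320225461,2,0.04601597719,FALSE
CE,675,-0.1191872685,0.03320140343,2,0.04601479751,FALSE
CE,685,-0.1191888554,0.03319942956,2,0.04601206188,FALSE
CE,695,-0.1191879253,0.03320184088,2,0.0460154038,FALSE
CE,705,-0.119187389,0.03320240622,2,0.04601618731,FALSE
CE,715,-0.1191879231,0.03320080121,2,0.04601396288,FALSE
CE,725,-0.1191878504,0.03320193916,2,0.04601554,FALSE
CE,735,-0.119187806,0.03320091924,2,0.04601412647,FALSE
CE,745,-0.1191880565,0.03320185002,2,0.04601541646,FALSE
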