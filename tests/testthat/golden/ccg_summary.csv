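ccg_id,window_start,window_end,n_practices,n_patients,items_total,cost_total,items_per_patient,cost_per_patient,share_metformin,share_sulphonylurea,share_TZD,share_DPP4,share_GLP1,share_SGLT2,share_other,share_non_met_non_su
CCG001,2016-09-01,2017-08-01,4,2149.9228999999996,24936,261586,11.598555464477357,121.67227020094536,56.42845684953481,28.119987167147897,1.3875521334616618,6.352261790182869,2.6628168110362527,4.9486685915944815,0.1002566570420276,15.451555983317292
CCG002,2016-09-01,2017-08-01,4,2195.4425,25464,327408,11.59857295283297,149.13075610042165,54.25699026076028,20.075400565504243,2.599748664781653,14.663839145460258,0.8325479107759974,6.943135406848884,0.6283380458686774,25.667609173735475
CCG003,2016-09-01,2017-08-01,3,1539.7921,17868,189394,11.604163964732642,122.99972184556604,57.52182672934856,23.74076561450638,3.447503917618088,10.851802104320573,1.4551152899037385,2.982986344302664,0,18.73740765614506
CCG004,2016-09-01,2017-08-01,4,1422.8455,16500,194101,11.596480433047722,136.41748172939367,57.03636363636364,18.21212121212121,6.581818181818182,11.466666666666667,1.284848484848485,5.418181818181819,0,24.75151515151515
CCG005,2016-09-01,2017-08-01,4,2532.1612000000005,29364,467511,11.59641811113763,184.62924082400437,54.99931889388366,13.673205285383464,1.8321754529355674,22.227898106524997,2.7686963628933388,4.20583026835581,0.2928756300231576,31.327475820732875
CCG006,2016-09-01,2017-08-01,4,1539.0079,17844,220690,11.594482393495186,143.3975745023791,60.2947769558395,18.762609280430397,1.776507509527012,13.954270342972427,2.8581035642232684,2.3369199731002017,0.016812373907195696,20.9426137637301
CCG007,2016-09-01,2017-08-01,2,893.2495999999999,10368,118079,11.607058094400491,132.19037545608754,57.00231481481482,24.720293209876544,0.7908950617283951,11.73804012345679,1.9579475308641976,3.7905092592592595,0,18.27739197530864
CCG008,2016-09-01,2017-08-01,4,1191.2350999999999,13800,171370,11.584614993295615,143.8590921305123,51.58695652173913,26.565217391304348,2.5869565217391304,14.53623188405797,2.7246376811594204,1.7391304347826086,0.26086956521739135,21.84782608695652
CCG009,2016-09-01,2017-08-01,3,1533.642,17784,203406,11.595926559131792,132.6293880840509,53.26698155645524,26.147098515519566,1.9793072424651372,15.491452991452991,0.7984705353126407,2.316689158794422,0,20.58591992802519
CCG010,2016-09-01,2017-08-01,2,766.685,8892,103133,11.59798352648089,134.51808761094844,58.77192982456141,20.928924876293298,1.540710751237067,15.384615384615385,1.282051282051282,2.0917678812415654,0,20.29914529914529
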