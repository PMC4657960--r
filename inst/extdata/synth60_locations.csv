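id,x,y,population
L001,35.6721999356523,91.8056417256594,86764.9872995193
L002,41.0635125823319,86.2629777053371,12522.7444838142
L003,57.3475898941979,31.6975237801671,31670.1036182229
L004,58.9678303571418,25.9260575985536,41475.6839243408
L005,71.9657292356715,74.226645193994,33000.1809293446
L006,39.4973045215011,74.736111680977,19808.6795929242
L007,91.9203929137439,91.7904034024104,99859.7516868688
L008,96.2570293573663,79.3191209202632,20037.1025534987
L009,23.3523525530472,13.3329618256539,165781.131739415
L010,72.4497599992901,28.7749752169475,20687.5200426423
L011,90.3634525137022,19.4676143815741,81216.1708095633
L012,60.3474084753543,78.4109382657334,216781.538998517
L013,63.1507298909128,12.8872161731124,5492.50271674988
L014,93.7385849654675,12.9089283524081,16667.4206410614
L015,85.0482750684023,7.22531112842262,19277.2064425225
L016,57.9820899059996,5.31294834800065,41603.9501832775
L017,82.1403923910111,53.1874436419457,16576.5956448075
L018,11.3718609092757,11.2308241659775,1546.182979847
L019,76.4507758663967,74.318771972321,1918.94929189478
L020,62.3613457195461,73.1315477285534,82463.6892991666
L021,14.8446606704965,88.5117687052116,16209.6399992167
L022,8.02644665818661,51.7111055552959,3709.64537960199
L023,46.4069551322609,85.1930984994397,18547.3582267291
L024,77.9368161456659,44.2796268267557,74211.5219297528
L025,73.352795955725,15.7880100421607,146560.480916472
L026,81.7230444401503,44.2324638832361,14321.6959876537
L027,17.0162481255829,96.7733667232096,17029.9803060823
L028,94.472032552585,48.4587929444388,3777.5726067346
L029,29.3623841367662,25.2458439441398,34894.9484733838
L030,14.9072052445263,25.9689980186522,11614.4480547875
L031,71.9378591282293,54.2015940882266,34733.1597924155
L032,32.4085952481255,64.9875837611035,44570.9391572104
L033,77.8809498529881,33.6419132305309,62013.2606103399
L034,39.4441001815721,6.09497462864965,11980.9554781223
L035,67.859286791645,45.1310850214213,36495.8970366739
L036,77.5825042743236,83.8755033444613,3956.01039710978
L037,18.7869044020772,57.4637334328145,10052.1416634022
L038,2.90858189109713,35.3350377408788,9405.89976378779
L039,13.5713797062635,54.7426078235731,1970.00695080529
L040,68.0164178134874,89.2718593822792,22836.6643045201
L041,93.48229537718,48.9990570582449,27065.0525323817
L042,55.0494084367529,17.1632113168016,15351.1044482237
L043,60.1766235427931,54.3030994012952,47012.2382784235
L044,19.699448812753,96.1467695888132,10649.7870211489
L045,53.5236610565335,31.3683822052553,5606.70765559715
L046,17.9555739276111,82.0514548104256,33955.9041773511
L047,45.1886494411156,30.7054400444031,9785.0092368795
L048,31.7053351784125,18.5453581158072,93349.0770299045
L049,11.6174670401961,4.83467767480761,14307.7095077358
L050,18.6102156760171,24.567414727062,42431.5676140414
L051,72.9730096645653,35.1106922142208,30391.7134150176
L052,41.187207121402,15.9022381762043,10058.376602586
L053,41.4049681741744,30.4097996791825,106481.604316749
L054,48.0310129001737,1.75483247730881,41894.0589931449
L055,42.7494465606287,99.6552679222077,24095.0245172815
L056,13.6490360135213,80.4393312660977,29043.5221369385
L057,82.4679406359792,8.6580601753667,43446.6408088263
L058,59.2304242542014,86.9933269685134,24096.7652042309
L059,79.4396977638826,55.4585863370448,1104.23704321556
L060,76.9032425712794,42.1378421830013,29286.5297421261
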