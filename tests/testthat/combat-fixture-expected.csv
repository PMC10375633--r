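subject_id,r1,r2,r3,r4,r5,r6
s01,125.660969101515,126.808620833889,124.484055748414,118.691063883710,123.024218915882,126.595484594547
s02,108.659169380525,123.030099665525,114.319173836614,109.341606306987,113.539174307282,116.980486751308
s03,120.796526550958,119.027143522021,121.269933168939,120.372608474206,115.689323621514,127.039387686500
s04,124.299978209045,118.465093751836,119.566354113825,125.372668349983,120.842142369846,121.456734089639
s05,109.083843954592,114.664754842008,122.124240519119,125.209341824920,114.299091956886,119.912613084039
s06,121.201034657453,117.444263819733,123.585410914621,122.602752171692,121.900461470194,124.900747227125
s07,110.780607533822,113.784257115761,111.592753166178,119.850733277988,111.979951594776,111.757639529919
s08,113.168224315935,108.630588400975,113.764237143731,114.191978645606,109.889128046586,113.804852453988
s09,122.790342576455,128.603230812211,119.071063401283,119.001052402037,122.419277626609,132.967236792389
s10,115.920177875752,110.310167750419,114.338323858849,111.873535274784,113.625206859175,115.282970116090
s11,123.280705225446,129.478005356030,127.912768662779,123.686247717862,121.104951446167,121.719306010036
s12,127.725656041353,126.082681519341,118.413945079309,129.972940820713,126.842837153424,114.557863855485
s13,121.943109404963,126.490618954617,121.915611841492,119.233814617378,118.431295234552,122.687124390333
s14,115.473926168909,120.410737077634,122.220720671276,113.733731371320,117.461951236205,116.753611035740
s15,113.903306977067,117.993221479769,116.109696737552,111.898411900558,122.081631225096,113.922412181607
s16,124.862128118928,123.853742216191,122.894651519518,128.164782235199,120.284519861737,125.038069880732
s17,106.669680206654,115.894913498919,109.803989759880,108.101325029266,105.725882450009,117.665901973987
s18,123.607480050123,123.122392486671,127.330626017857,124.174372447513,125.508073106856,124.231531647939
s19,112.212278493735,102.931104679566,106.476504445836,108.761714229743,111.494941163868,111.032528486295
s20,120.715190340072,115.829314261448,112.068453287874,107.096922724495,112.252485743766,120.288053624704
s21,104.300104515956,110.515821048770,106.955697124453,116.833379761121,110.769325880423,108.011287800802
s22,110.428752882772,102.102968054883,113.362299829137,112.737210679036,105.577853090324,108.162137944564
s23,121.493338991818,124.378561282549,123.013070603510,119.943418230881,117.494053791944,121.498961609970
s24,125.850184907188,118.898439668865,116.149746717348,127.426661416656,129.543307869437,117.068652771390
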