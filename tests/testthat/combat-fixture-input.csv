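subject_id,batch,age,sex,r1,r2,r3,r4,r5,r6
s01,1,17.554,1,122.653202,123.620772,122.248264,116.401525,120.003726,124.521005
s02,1,9.813,0,105.60099,119.537405,112.076675,107.058598,110.46133,114.700416
s03,1,15.205,1,117.773201,116.027844,119.030641,118.126963,113.031295,125.186666
s04,1,15.473,1,121.306392,115.504756,117.316564,123.173687,117.778442,119.121109
s05,1,11.855,0,106.003111,111.639223,119.911161,123.060647,111.38024,117.71423
s06,1,15.521,0,118.187504,114.515077,121.359082,120.385731,118.740566,122.826195
s07,1,11.236,0,107.724025,110.759608,109.327775,117.655864,109.189221,108.933445
s08,1,9.548,0,110.15626,105.723157,111.520331,111.960307,107.090432,111.282971
s09,1,18.149,0,119.757676,125.360774,116.805961,116.717802,119.502761,131.352921
s10,1,6.786,1,112.960196,107.186955,112.110636,109.64064,110.221433,113.120961
s11,1,18.528,1,120.237684,126.235215,125.689461,121.435162,118.3529,119.164748
s12,1,19.297,1,124.714782,123.02604,116.136246,127.775532,123.690474,111.350341
s13,2,15.553,0,125.012927,130.035388,124.258833,121.416777,121.064734,124.980557
s14,2,12.737,1,118.327354,123.72519,124.724698,115.733374,120.431323,119.061354
s15,2,11.742,0,116.807316,121.243879,118.359388,113.91692,125.853628,116.240263
s16,2,17.633,1,127.873056,126.860583,125.138849,130.658848,122.787595,127.328591
s17,2,6.655,1,109.496153,119.569593,111.982253,110.181997,108.182912,119.941768
s18,2,17.948,1,126.518836,126.022048,129.804084,126.422097,128.649911,126.527314
s19,2,6.966,1,115.340701,105.377184,108.449539,110.8593,114.663776,113.341343
s20,2,9.431,0,124.208475,119.175758,114.23228,108.995728,115.117564,122.565173
s21,2,5.709,1,107.063352,113.817598,109.03195,119.469973,114.057752,110.328776
s22,2,6.68,0,113.537754,104.54075,115.76575,115.135676,108.029978,110.484457
s23,2,15.207,0,124.564639,127.773674,125.438772,122.189236,120.062588,123.796477
s24,2,17.75,0,128.972633,121.467139,118.036589,129.928589,133.273399,119.398748
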