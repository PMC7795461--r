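classifier,acc_global,cov_global,acc_156,acc_7,acc_balanced,tpr_156,tpr_7
canberra.1nn,0.757892,1,0.881348,0.434096,0.65772,0.808972,0.589808
canberra.811,0.469476,1,0.408336,0.65762,0.532972,0.673972,0.302018
eps=0.01.nb,0.635784,1,0.818772,0.157048,0.487912,0.726604,0.195856
eps=0.01.nb2,0.477892,1,0.471108,0.51562,0.493364,0.737268,0.250017
euclidean.1nn,0.766312,1,0.858332,0.53524,0.696788,0.834828,0.608952
euclidean.811,0.50316,1,0.409024,0.763432,0.586228,0.808416,0.360549
manhattan.1nn,0.732632,1,0.841324,0.45848,0.649904,0.809468,0.527712
manhattan.811,0.4779,1,0.391062,0.720764,0.555908,0.749288,0.32875
maxminnormalized.1nn,0.741056,1,0.85872,0.434096,0.646404,0.804592,0.515332
maxminnormalized.811,0.503164,1,0.467176,0.603336,0.535252,0.739672,0.326092
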