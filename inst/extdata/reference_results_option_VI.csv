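classifier,acc_global,cov_global,acc_156,acc_7,acc_balanced,tpr_156,tpr_7
canberra.1nn,0.732624,1,0.850236,0.454,0.65212,0.798528,0.594572
canberra.811,0.59158,1,0.447148,0.975,0.711076,0.986668,0.428288
eps=0.01.nb,0.654732,1,0.826652,0.253952,0.540308,0.735512,0.396762
eps=0.01.nb2,0.532628,1,0.483588,0.67662,0.580104,0.786232,0.342526
euclidean.1nn,0.751572,1,0.843516,0.55976,0.70164,0.833768,0.559636
euclidean.811,0.738944,1,0.85024,0.450952,0.6506,0.81728,0.650192
manhattan.1nn,0.74526,1,0.820408,0.588192,0.704296,0.840516,0.588724
manhattan.811,0.730524,1,0.810488,0.540284,0.675384,0.832588,0.589084
maxminnormalized.1nn,0.741048,1,0.85594,0.469048,0.662496,0.803396,0.612092
maxminnormalized.811,0.71368,1,0.694484,0.789996,0.74224,0.915252,0.5277
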