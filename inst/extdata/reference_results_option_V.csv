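classifier,acc_global,cov_global,acc_156,acc_7,acc_balanced,tpr_156,tpr_7
canberra.1nn,0.770524,1,0.944852,0.347047,0.645948,0.790696,0.622
canberra.811,0.604212,1,0.465928,0.984,0.724968,0.994668,0.404204
eps=0.01.nb,0.621048,1,0.692736,0.524856,0.6088,0.795492,0.367568
eps=0.01.nb2,0.543152,1,0.469512,0.804,0.636764,0.867452,0.341942
euclidean.1nn,0.80842,1,0.934388,0.51124,0.722808,0.837764,0.710188
euclidean.811,0.669476,1,0.592276,0.881712,0.736984,0.943892,0.450932
manhattan.1nn,0.778948,1,0.942352,0.383333,0.662844,0.800552,0.654
manhattan.811,0.658944,1,0.543292,0.978284,0.76078,0.990224,0.442968
maxminnormalized.1nn,0.755788,1,0.938508,0.306285,0.622388,0.780056,0.562004
maxminnormalized.811,0.610528,1,0.485748,0.957904,0.721832,0.980056,0.403856
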