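classifier,acc_global,cov_global,acc_156,acc_7,acc_balanced,tpr_156,tpr_7
canberra.1nn,0.804204,1,0.941696,0.421144,0.681416,0.831952,0.718668
canberra.811,0.59578,1,0.46676,1,0.73338,1,0.386401
eps=0.01.nb,0.639988,1,0.436116,0.57086,0.631352,0.831816,0.385934
eps=0.01.nb2,0.522104,1,0.930472,0.838284,0.6372,0.903864,0.331623
euclidean.1nn,0.835788,1,0.930472,0.59462,0.762544,0.871184,0.742336
euclidean.811,0.66526,1,0.589488,0.892668,0.741072,0.962496,0.42656
manhattan.1nn,0.802104,1,0.928148,0.488048,0.708096,0.840752,0.637808
manhattan.811,0.61894,1,0.50308,0.968668,0.73588,0.989336,0.395088
maxminnormalized.1nn,0.776836,1,0.941556,0.324333,0.632944,0.806192,0.580668
maxminnormalized.811,0.59578,1,0.474112,0.978668,0.726392,0.989848,0.38302
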