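Code,AutoDock,Vina,SMINA/vina,SMINA/vinardo,SMINA/ad4,DOCK,PLANTS/chemplp,PLANTS/plp,PLANTS/plp95
6A93,2.784,2.843,2.742,2.563,3.563,3.231,2.573,2.742,2.746
6A94,2.657,2.224,3.241,3.431,3.431,3.422,2.991,2.664,2.561
6WGT,2.943,1.943,2.941,2.567,2.567,2.993,2.892,3.245,2.993
6WH4,2.995,1.971,2.518,2.783,2.783,2.961,2.973,2.835,3.762
6WHA,3.726,2.941,3.663,3.452,3.452,2.693,2.116,2.985,3.426
7RAN,3.651,2.365,2.632,2.954,3.954,3.652,2.639,2.954,3.624
7VOD,3.648,1.984,3.654,3.642,3.642,2.584,2.652,2.667,3.621
7VOE,6.257,1.965,2.548,2.984,2.984,2.524,2.547,2.647,2.457
7WC4,3.658,2.695,2.458,2.658,2.658,3.632,3.698,3.965,3.621
7WC5,2.398,2.657,2.654,2.984,2.984,3.324,3.258,3.541,2.514
7WC6,3.695,3.625,3.254,3.652,3.652,2.659,2.987,2.564,2.558
7WC7,2.698,3.954,2.698,2.874,2.874,2.584,2.898,2.842,2.774
7WC8,3.654,3.625,2.548,2.636,2.636,3.395,2.235,2.665,2.664
7WC9,3.658,3.695,2.547,2.584,2.584,2.987,2.397,2.635,2.981
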