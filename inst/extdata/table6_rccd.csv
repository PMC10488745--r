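Code,AutoDock,Vina,SMINA/vina,SMINA/vinardo,SMINA/ad4,DOCK,PLANTS/chemplp,PLANTS/plp,PLANTS/plp95
4NC3,4.454,2.785,2.986,2.784,2.984,4.313,3.125,2.742,3.421
4IB4,3.431,2.895,4.124,3.984,2.634,3.453,3.784,2.563,2.741
5TUD,3.625,2.748,2.642,3.614,3.569,3.695,2.539,2.597,3.625
5TVN,2.895,1.993,1.963,1.943,3.964,3.241,2.431,3.254,2.346
6DRX,2.674,2.864,2.424,2.435,2.874,3.254,2.964,3.541,2.758
6DRY,2.895,2.998,3.894,3.784,2.695,2.451,2.531,2.431,2.321
6DRZ,2.992,2.674,3.431,3.895,3.624,2.563,2.728,3.522,2.462
6DS0,2.567,1.864,2.974,2.983,2.874,2.451,2.351,2.214,3.325
7SQR,2.517,2.957,2.987,2.524,2.595,3.648,2.487,2.845,2.635
7SRS,2.698,1.997,1.987,1.987,2.749,2.874,2.228,2.457,3.984
7SRR,3.624,2.487,2.964,1.987,2.996,3.625,2.487,2.625,3.635
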