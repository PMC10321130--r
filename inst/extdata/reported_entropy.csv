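clusterer,apen_A,apen_E,shannon_A,shannon_E,sampen_A,sampen_E
kmeans,1.37,1.19,1.46,1.24,5.429,6.15
fcm,1.42,1.15,1.58,1.27,5.23,6.34
cuckoo,1.86,1.07,1.92,0.864,4.1774,6.82
dragonfly,1.79,1.246,1.83,1.12,4.637,5.96
firefly,1.65,1.058,1.75,1.034,5.407,6.12
modified_firefly,1.39,1.217,1.86,1.17,4.8019,6.45
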