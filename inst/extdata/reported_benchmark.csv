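clusterer,classifier,sensitivity,specificity,accuracy
kmeans,ann,56.57656,100,78.28828
kmeans,knn,71.875,100,85.9375
kmeans,ilda,61.46,100,80.73
kmeans,nbc,100,97.92,98.96
kmeans,svm_linear,97.92,100,98.96
kmeans,svm_poly,94.79,100,97.395
kmeans,svm_rbf,92.71,100,96.355
kmeans,qda,91.41,100,95.705
kmeans,dtree,69.795,100,84.8975
kmeans,rf,100,80.225,90.1125
fcm,ann,64.19,100,82.095
fcm,knn,100,89.59,94.795
fcm,ilda,100,85.42,92.71
fcm,nbc,100,89.0675,94.53375
fcm,svm_linear,90.11,100,95.055
fcm,svm_poly,95.31,100,97.655
fcm,svm_rbf,100,77.625,88.8125
fcm,qda,100,96.875,98.4375
fcm,dtree,97.92,100,98.96
fcm,rf,73.4375,100,86.71875
cuckoo,ann,87.5,100,93.75
cuckoo,knn,82.94813,100,91.47406
cuckoo,ilda,75,100,87.5
cuckoo,nbc,100,96.3525,98.17625
cuckoo,svm_linear,98.96,100,99.48
cuckoo,svm_poly,91.67,100,95.835
cuckoo,svm_rbf,67.969,100,83.9845
cuckoo,qda,70.05625,100,85.02813
cuckoo,dtree,65.232,100,82.616
cuckoo,rf,100,90.11,95.055
dragonfly,ann,80.7375,100,90.36875
dragonfly,knn,51,100,75.5
dragonfly,ilda,65.884,100,82.942
dragonfly,nbc,62.5,100,81.25
dragonfly,svm_linear,80.225,100,90.1125
dragonfly,svm_poly,100,81.25,90.625
dragonfly,svm_rbf,94.79,100,97.395
dragonfly,qda,93.75,100,96.875
dragonfly,dtree,91.15,100,95.575
dragonfly,rf,77.625,100,88.8125
firefly,ann,100,68.75,84.375
firefly,knn,59.38,100,79.69
firefly,ilda,100,83.86,91.93
firefly,nbc,51.5,100,75.75
firefly,svm_linear,100,84.38,92.19
firefly,svm_poly,66.699,100,83.3495
firefly,svm_rbf,79.7125,100,89.85625
firefly,qda,71.09875,100,85.54938
firefly,dtree,89.59,100,94.795
firefly,rf,100,78.4125,89.20625
modified_firefly,ann,57.42563,100,78.71281
modified_firefly,knn,100,89.59,94.795
modified_firefly,ilda,100,96.3525,98.17625
modified_firefly,nbc,100,91.41,95.705
modified_firefly,svm_linear,95.31,100,97.655
modified_firefly,svm_poly,95.83,100,97.915
modified_firefly,svm_rbf,100,65.884,82.942
modified_firefly,qda,100,80.225,90.1125
modified_firefly,dtree,56.7725,100,78.38625
modified_firefly,rf,71.68094,100,85.84047
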