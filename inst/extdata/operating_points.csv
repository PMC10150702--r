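method,task,sensitivity_pct,specificity_pct
observer1,binary,75,89
observer2,binary,91,83
svm,II,81,89
cnn,I,59,77
cnn,II,84,79
cnn,III,87,79
aefc,I,65,66
aefc,II,86,83
aefc,III,90,84
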