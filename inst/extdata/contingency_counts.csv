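study,tp,fp,tn,fn
fna,5,0,9,7
mri,9,0,9,3
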