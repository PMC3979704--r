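study,approach,tp,fn,tn,fp
Merged data,,736,5,11601,6
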