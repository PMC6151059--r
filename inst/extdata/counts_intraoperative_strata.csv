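label,score,events,nonevents
low,1,0,15
moderate,2,15,75
high,3,10,23
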