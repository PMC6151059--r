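label,score,events,nonevents
low,1,7,8
moderate,2,32,58
high,3,14,19
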