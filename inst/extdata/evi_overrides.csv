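archetype,phase,field,value
unprecedented,phase1,prob_success,0.7
unprecedented,phase1,length,1.45
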