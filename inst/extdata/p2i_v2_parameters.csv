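archetype,phase,cost_musd,length_years,prob_success
complex,preclinical,16.6,3.3,41%
complex,phase1,2.5,2,50%
complex,phase2,13.9,3.7,22%
complex,phase3,223,3.5,64%
simple,preclinical,6.7,3.4,41%
simple,phase1,2.2,1.6,68%
simple,phase2,13.2,2.2,46%
simple,phase3,201,2.3,71%
unprecedented,preclinical,16.6,3.3,41%
unprecedented,phase1,2.5,2,50%
unprecedented,phase2,13.9,3.7,5%
unprecedented,phase3,223,3.5,40%
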