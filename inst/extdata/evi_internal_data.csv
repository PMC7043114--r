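"stage","n","value","unit","archetypes","applied"
"preclinical duration",2,36,"months","all unprecedented",FALSE
"preclinical cost",3,2483333,"EUR","1 simple, 2 unprecedented",FALSE
"phase1 technical success",10,1,"fraction","all unprecedented",FALSE
"phase1 transition success",10,0.7,"fraction","all unprecedented",TRUE
"phase1 duration",10,17.4,"months","all unprecedented",TRUE
"phase1 cost",3,1500000,"EUR","all unprecedented",FALSE
"phase2 technical success",2,1,"fraction","all unprecedented",FALSE
"phase2 transition success",2,1,"fraction","all unprecedented",FALSE
"phase2 duration",2,22.5,"months","all unprecedented",FALSE
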