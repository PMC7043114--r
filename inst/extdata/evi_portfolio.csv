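"candidate_id","disease","archetype","entry_phase"
"Malaria 1","malaria","unprecedented","phase2"
"Malaria 2","malaria","unprecedented","phase1"
"Malaria 3","malaria","unprecedented","phase1"
"Malaria 4","malaria","unprecedented","phase2"
"Malaria 5","malaria","unprecedented","phase2"
"Malaria 6","malaria","unprecedented","preclinical"
"Malaria 7","malaria","unprecedented","preclinical"
"Malaria 8","placental malaria","unprecedented","phase1"
"Malaria 9","placental malaria","unprecedented","phase1"
"Malaria 10","malaria","unprecedented","phase1"
"Malaria 11","placental malaria","unprecedented","phase1"
"Malaria 12","placental malaria","unprecedented","phase1"
"Malaria 13","placental malaria","unprecedented","phase1"
"Zika 1","Zika","simple","phase1"
"Nipah 1","Nipah","simple","phase1"
"Diarrheal disease 1","shigellosis, ETEC","complex","phase1"
"Leishmaniasis 1","leishmaniasis","unprecedented","preclinical"
"Leishmaniasis 2","leishmaniasis","unprecedented","phase2"
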