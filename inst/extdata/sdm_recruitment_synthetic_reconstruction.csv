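trial_id,intervention_id,level_order,unit_label,participated,approached,population_based
sdm1,shared_decision_making,1,clinician,45,345,TRUE
sdm2,shared_decision_making,1,clinician,101,2036,TRUE
sdm3r,shared_decision_making,1,clinician,135,1008,TRUE
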