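trial_id,intervention_id,level_order,unit_label,participated,approached,population_based
dp1,delayed_prescribing,1,practice,22,61,TRUE
dp1,delayed_prescribing,2,clinician,48,92,TRUE
pct1,procalcitonin,1,clinician,53,345,TRUE
crp1,crp,1,clinician,35,125,TRUE
sdm1,shared_decision_making,1,clinician,45,345,TRUE
sdm2,shared_decision_making,1,clinician,101,2036,TRUE
sdm3,shared_decision_making,1,practice,4,24,TRUE
sdm3,shared_decision_making,2,clinician,33,42,TRUE
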