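intervention_id,rr,ci_low,ci_high
delayed_prescribing,0.36,0.27,0.48
procalcitonin,0.39,0.17,0.86
crp,0.78,0.66,0.92
shared_decision_making,0.61,0.55,0.68
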