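trial_id,intervention_id,events_t,n_t,events_c,n_c
delayed_total,delayed_prescribing,255,817,790,847
procalcitonin_total,procalcitonin,117,507,320,501
crp_total,crp,631,1685,785,1599
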