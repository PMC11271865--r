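patient_id,course,effective_date
confirmed,RR,2002-03-29
short_history,RR,2002-03-29
unconfirmable,RR,2002-03-29
regressed,RR,2002-03-29
no_progression,RR,2002-03-29
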