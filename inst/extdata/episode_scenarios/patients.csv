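patient_id,center_id,sex,birth_date,ms_onset_date,diagnosis_date,education,first_symptom
confirmed,C1,F,1980-05-03,1999-07-03,2000-01-19,NA,NA
short_history,C1,F,1980-05-03,1999-07-03,2000-01-19,NA,NA
unconfirmable,C1,F,1980-05-03,1999-07-03,2000-01-19,NA,NA
regressed,C1,F,1980-05-03,1999-07-03,2000-01-19,NA,NA
no_progression,C1,F,1980-05-03,1999-07-03,2000-01-19,NA,NA
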