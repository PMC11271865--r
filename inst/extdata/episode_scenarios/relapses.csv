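patient_id,onset_date,pos_pyramidal_tract,pos_brainstem,pos_bowel_bladder,pos_cerebellum,pos_visual_function,pos_sensory
confirmed,2012-11-06,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE
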