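patient_id,visit_date,edss,kfs_pyramidal,kfs_cerebellar,kfs_brainstem,kfs_sensory,kfs_sphincteric,kfs_visual,kfs_cerebral,kfs_ambulatory
confirmed,2007-12-28,3,NA,NA,NA,NA,NA,NA,NA,NA
confirmed,2008-12-12,3,NA,NA,NA,NA,NA,NA,NA,NA
confirmed,2009-12-17,3,NA,NA,NA,NA,NA,NA,NA,NA
confirmed,2010-06-15,3,NA,NA,NA,NA,NA,NA,NA,NA
confirmed,2012-06-14,4,NA,NA,NA,NA,NA,NA,NA,NA
confirmed,2012-11-11,4,NA,NA,NA,NA,NA,NA,NA,NA
confirmed,2014-06-15,4,NA,NA,NA,NA,NA,NA,NA,NA
short_history,2009-12-17,3,NA,NA,NA,NA,NA,NA,NA,NA
short_history,2010-06-15,3,NA,NA,NA,NA,NA,NA,NA,NA
short_history,2011-12-15,4,NA,NA,NA,NA,NA,NA,NA,NA
short_history,2012-08-23,4,NA,NA,NA,NA,NA,NA,NA,NA
short_history,2013-06-19,4,NA,NA,NA,NA,NA,NA,NA,NA
unconfirmable,2007-12-28,3,NA,NA,NA,NA,NA,NA,NA,NA
unconfirmable,2008-12-12,3,NA,NA,NA,NA,NA,NA,NA,NA
unconfirmable,2009-12-17,3,NA,NA,NA,NA,NA,NA,NA,NA
unconfirmable,2010-06-15,3,NA,NA,NA,NA,NA,NA,NA,NA
unconfirmable,2012-04-02,4.5,NA,NA,NA,NA,NA,NA,NA,NA
regressed,2007-12-28,3,NA,NA,NA,NA,NA,NA,NA,NA
regressed,2008-12-12,3,NA,NA,NA,NA,NA,NA,NA,NA
regressed,2009-12-17,3,NA,NA,NA,NA,NA,NA,NA,NA
regressed,2010-06-15,3,NA,NA,NA,NA,NA,NA,NA,NA
regressed,2012-05-09,4,NA,NA,NA,NA,NA,NA,NA,NA
regressed,2012-08-26,3,NA,NA,NA,NA,NA,NA,NA,NA
no_progression,2007-12-28,3,NA,NA,NA,NA,NA,NA,NA,NA
no_progression,2008-12-12,3,NA,NA,NA,NA,NA,NA,NA,NA
no_progression,2009-12-17,3,NA,NA,NA,NA,NA,NA,NA,NA
no_progression,2010-06-15,3,NA,NA,NA,NA,NA,NA,NA,NA
no_progression,2011-12-15,3,NA,NA,NA,NA,NA,NA,NA,NA
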