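visit_type_id,cohort,centre_class,item_id,count
baseline,HAP,AMC,doc-screening-baseline,1
baseline,HAP,AMC,doc-clinical-status,1
baseline,HAP,AMC,ecg,1
baseline,HAP,AMC,pbmc,1
baseline,HAP,AMC,echo,1
ward-day,HAP,AMC,doc-ward,1
ward-day,HAP,AMC,doc-clinical-status,1
icu-day,HAP,AMC,doc-icu,1
icu-day,HAP,AMC,doc-clinical-status,1
discharge,HAP,AMC,doc-clinical-status,1
discharge,HAP,AMC,ecg,1
discharge,HAP,AMC,spirometry,1
fu-3mo,HAP,AMC,doc-clinical-status,1
fu-3mo,HAP,AMC,spirometry,1
fu-3mo,HAP,AMC,pbmc,1
fu-12mo,HAP,AMC,doc-clinical-status,1
fu-12mo,HAP,AMC,spirometry,1
pop-initial-interview,POP,AMC,doc-clinical-status,1
pop-onsite,POP,AMC,doc-screening-baseline,1
pop-onsite,POP,AMC,ecg,1
pop-onsite,POP,AMC,spirometry,1
pop-onsite,POP,AMC,pbmc,1
pop-onsite,POP,AMC,echo,1
baseline,SUEP,AMC,doc-screening-baseline,1
baseline,SUEP,AMC,ecg,1
baseline,SUEP,AMC,pbmc,1
baseline,SUEP,AMC,echo,1
ward-day,SUEP,AMC,doc-ward,1
icu-day,SUEP,AMC,doc-icu,1
discharge,SUEP,AMC,doc-clinical-status,1
discharge,SUEP,AMC,ecg,1
fu-3mo,SUEP,AMC,doc-clinical-status,1
fu-3mo,SUEP,AMC,pbmc,1
fu-12mo,SUEP,AMC,doc-clinical-status,1
baseline,SUEP,non-AMC,doc-screening-baseline,1
baseline,SUEP,non-AMC,ecg,1
ward-day,SUEP,non-AMC,doc-ward,1
discharge,SUEP,non-AMC,doc-clinical-status,1
fu-3mo,SUEP,non-AMC,doc-clinical-status,1
fu-12mo,SUEP,non-AMC,doc-clinical-status,1
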