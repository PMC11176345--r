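cohort,centre_class,display_letter,n_reimbursable,mean_per_case_eur,target_cases,ufam_per_case_eur
HAP,AMC,A,164,6797.53,73.5,NA
HAP,AMC,D,102,3876.32,73.5,NA
HAP,AMC,J,4,1901.91,73.5,240320.49
POP,AMC,A,301,2804.74,330,NA
POP,AMC,B,348,2756.18,330,NA
POP,AMC,C,1663,2658.20,660,NA
SUEP,AMC,A,86,3479.29,98.1,NA
SUEP,AMC,E,110,2793.60,98.1,NA
SUEP,AMC,J,3,2293.73,98.1,NA
SUEP,AMC,Y,60,980.30,98.1,NA
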