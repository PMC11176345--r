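item_id,label,data_points,material_cost_eur,overhead_rate,printed_total_eur,role,minutes,salary_percent,explicit_cost_eur
doc-screening-baseline,Documentation screening and baseline,400,0,0,115.00,SP,183,0.18,101.00
doc-screening-baseline,Documentation screening and baseline,400,0,0,115.00,PH,18.3,0.02,15.00
doc-ward,Documentation hospital ward,100,0,0,66.00,SP,105,0.10,58.00
doc-ward,Documentation hospital ward,100,0,0,66.00,PH,10.5,0.01,8.00
doc-icu,Documentation ICU,200,0,0,123.00,SP,195,0.19,107.00
doc-icu,Documentation ICU,200,0,0,123.00,PH,19.5,0.02,16.00
doc-clinical-status,Document clinical status,NA,0,0,5.50,SP,10,0.01,5.50
ecg,Electrocardiography,NA,1.00,0,17.67,SP,10,0.01,5.50
ecg,Electrocardiography,NA,1.00,0,17.67,MS,10,0.01,11.17
pbmc,PBMCs from 9 ml EDTA,NA,5.00,0,70.97,SP,120,0.12,65.97
spirometry,Spirometry with plethysmograph and diffusion measurement,NA,70.00,0,203.80,SP,90,0.09,49.48
spirometry,Spirometry with plethysmograph and diffusion measurement,NA,70.00,0,203.80,PH,60,0.06,48.16
spirometry,Spirometry with plethysmograph and diffusion measurement,NA,70.00,0,203.80,MS,30,0.03,36.16
echo,Transthoracic echocardiogram,NA,25.00,0,83.52,SP,15,0.01,8.25
echo,Transthoracic echocardiogram,NA,25.00,0,83.52,MS,45,0.04,50.28
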