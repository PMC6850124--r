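covariate,level,count,share,source,denominator
age,65-74,4524,45.7,control,9906
age,>=75,5382,54.3,control,9906
age,65-74,2580,48.2,rpm,5348
age,>=75,2768,51.8,rpm,5348
age,65-74,7104,46.6,total,15254
age,>=75,8150,53.4,total,15254
nyha,I/II,3348,33.8,control,9906
nyha,III/IV,6552,66.1,control,9906
nyha,I/II,1651,30.9,rpm,5348
nyha,III/IV,3690,69.0,rpm,5348
nyha,I/II,4999,32.8,total,15254
nyha,III/IV,10242,67.1,total,15254
sex,male,7104,71.7,control,9906
sex,female,2802,28.3,control,9906
sex,male,3846,71.9,rpm,5348
sex,female,1502,28.1,rpm,5348
sex,male,10950,71.8,total,15254
sex,female,4304,28.2,total,15254
race,white,8270,83.5,control,9906
race,black,786,7.9,control,9906
race,hispanic,486,4.9,control,9906
race,other,352,3.6,control,9906
race,white,4789,89.5,rpm,5348
race,black,323,6.0,rpm,5348
race,hispanic,111,2.1,rpm,5348
race,other,120,2.2,rpm,5348
race,white,13059,85.6,total,15254
race,black,1109,7.3,total,15254
race,hispanic,597,3.9,total,15254
race,other,472,3.1,total,15254
admission_reason,procedure,5839,58.9,control,9906
admission_reason,cardiac,1571,15.9,control,9906
admission_reason,noncardiac,2118,21.4,control,9906
admission_reason,unknown,361,3.6,control,9906
admission_reason,procedure,3518,65.8,rpm,5348
admission_reason,cardiac,656,12.3,rpm,5348
admission_reason,noncardiac,1054,19.7,rpm,5348
admission_reason,unknown,117,2.2,rpm,5348
admission_reason,procedure,9357,61.3,total,15254
admission_reason,cardiac,2227,14.6,total,15254
admission_reason,noncardiac,3172,20.8,total,15254
admission_reason,unknown,478,3.1,total,15254
chf_duration,none,1426,14.4,control,9906
chf_duration,<9mo,2543,25.7,control,9906
chf_duration,>9mo,5932,59.9,control,9906
chf_duration,none,762,14.2,rpm,5348
chf_duration,<9mo,1386,25.9,rpm,5348
chf_duration,>9mo,3190,59.6,rpm,5348
chf_duration,none,2188,14.3,total,15254
chf_duration,<9mo,3929,25.8,total,15254
chf_duration,>9mo,9122,59.8,total,15254
chf_hospitalization,none,5141,51.9,control,9906
chf_hospitalization,<6mo,2856,28.8,control,9906
chf_hospitalization,>6mo,1898,19.2,control,9906
chf_hospitalization,none,3022,56.5,rpm,5348
chf_hospitalization,<6mo,1334,24.9,rpm,5348
chf_hospitalization,>6mo,977,18.3,rpm,5348
chf_hospitalization,none,8163,53.5,total,15254
chf_hospitalization,<6mo,4190,27.5,total,15254
chf_hospitalization,>6mo,2875,18.8,total,15254
af_flutter,yes,4025,40.6,control,9906
af_flutter,yes,2066,38.6,rpm,5348
af_flutter,yes,6091,39.9,total,15254
nidcm,none,7070,71.4,control,9906
nidcm,<9mo,977,9.9,control,9906
nidcm,>9mo,1854,18.7,control,9906
nidcm,none,3668,68.6,rpm,5348
nidcm,<9mo,555,10.4,rpm,5348
nidcm,>9mo,1122,21.0,rpm,5348
nidcm,none,10738,70.4,total,15254
nidcm,<9mo,1532,10.0,total,15254
nidcm,>9mo,2976,19.5,total,15254
cabg_pci,yes,4350,43.9,control,9906
cabg_pci,yes,2292,42.9,rpm,5348
cabg_pci,yes,6642,43.5,total,15254
pacemaker,yes,1535,15.5,control,9906
pacemaker,yes,786,14.7,rpm,5348
pacemaker,yes,2321,15.2,total,15254
cerebrovascular,yes,1683,17.0,control,9906
cerebrovascular,yes,854,16.0,rpm,5348
cerebrovascular,yes,2537,16.6,total,15254
lung_disease,yes,2589,26.1,control,9906
lung_disease,yes,1325,24.8,rpm,5348
lung_disease,yes,3914,25.7,total,15254
diabetes,yes,4015,40.5,control,9906
diabetes,yes,1958,36.6,rpm,5348
diabetes,yes,5973,39.2,total,15254
hypertension,yes,8054,81.3,control,9906
hypertension,yes,4312,80.6,rpm,5348
hypertension,yes,12366,81.1,total,15254
dialysis,yes,425,4.3,control,9906
dialysis,yes,131,2.4,rpm,5348
dialysis,yes,556,3.6,total,15254
qrs,<=120,3483,35.2,control,9906
qrs,>120,6423,64.8,control,9906
qrs,<=120,1705,31.9,rpm,5348
qrs,>120,3643,68.1,rpm,5348
qrs,<=120,5188,34.0,total,15254
qrs,>120,10066,66.0,total,15254
ivc,normal,2789,28.2,control,9906
ivc,lbbb,3625,36.6,control,9906
ivc,rbbb,880,8.9,control,9906
ivc,paced,1047,10.6,control,9906
ivc,other,1551,15.7,control,9906
ivc,normal,1380,25.8,rpm,5348
ivc,lbbb,2179,40.7,rpm,5348
ivc,rbbb,434,8.1,rpm,5348
ivc,paced,539,10.1,rpm,5348
ivc,other,810,15.1,rpm,5348
ivc,normal,4169,27.3,total,15254
ivc,lbbb,5804,38.0,total,15254
ivc,rbbb,1314,8.6,total,15254
ivc,paced,1586,10.4,total,15254
ivc,other,2361,15.5,total,15254
creatinine,<=1.5,7449,75.2,control,9906
creatinine,1.5-2.5,1887,19.0,control,9906
creatinine,>2.5,555,5.6,control,9906
creatinine,<=1.5,4117,77.0,rpm,5348
creatinine,1.5-2.5,1013,18.9,rpm,5348
creatinine,>2.5,208,3.9,rpm,5348
creatinine,<=1.5,11566,75.8,total,15254
creatinine,1.5-2.5,2900,19.0,total,15254
creatinine,>2.5,763,5.0,total,15254
bun,<=20,3889,39.3,control,9906
bun,20-40,4618,46.6,control,9906
bun,>40,1379,13.9,control,9906
bun,<=20,2226,41.6,rpm,5348
bun,20-40,2465,46.1,rpm,5348
bun,>40,645,12.1,rpm,5348
bun,<=20,6115,40.1,total,15254
bun,20-40,7083,46.4,total,15254
bun,>40,2024,13.3,total,15254
sodium,<=135,1687,17.0,control,9906
sodium,135-145,8070,81.5,control,9906
sodium,>145,123,1.2,control,9906
sodium,<=135,826,15.4,rpm,5348
sodium,135-145,4459,83.4,rpm,5348
sodium,>145,51,1.0,rpm,5348
sodium,<=135,2513,16.5,total,15254
sodium,135-145,12529,82.1,total,15254
sodium,>145,174,1.1,total,15254
sbp,<=100,635,6.4,control,9906
sbp,100-130,4393,44.3,control,9906
sbp,>130,4826,48.7,control,9906
sbp,<=100,326,6.1,rpm,5348
sbp,100-130,2217,41.5,rpm,5348
sbp,>130,2786,52.1,rpm,5348
sbp,<=100,961,6.3,total,15254
sbp,100-130,6610,43.3,total,15254
sbp,>130,7612,49.9,total,15254
icd_type,single,1102,11.1,control,9906
icd_type,dual,2737,27.6,control,9906
icd_type,biventricular,6054,61.1,control,9906
icd_type,single,420,7.9,rpm,5348
icd_type,dual,1334,24.9,rpm,5348
icd_type,biventricular,3590,67.1,rpm,5348
icd_type,single,1522,10.0,total,15254
icd_type,dual,4071,26.7,total,15254
icd_type,biventricular,9644,63.2,total,15254
teaching,coth,277,2.8,control,9906
teaching,teaching,2782,28.1,control,9906
teaching,other,2466,24.9,control,9906
teaching,coth,208,3.9,rpm,5348
teaching,teaching,1412,26.4,rpm,5348
teaching,other,1298,24.3,rpm,5348
teaching,coth,485,3.2,total,15254
teaching,teaching,4194,27.5,total,15254
teaching,other,3764,24.7,total,15254
pop_density,<=3000,8747,88.3,control,9906
pop_density,>3000,1122,11.3,control,9906
pop_density,<=3000,4972,93.0,rpm,5348
pop_density,>3000,356,6.7,rpm,5348
pop_density,<=3000,13719,89.9,total,15254
pop_density,>3000,1478,9.7,total,15254
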