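endpoint,covariate,level,coefficient,se,p
rehosp,(scale),,1.2024,0.0128,
rehosp,(shape),,0.8316,0.0088,
rehosp,(intercept),,7.5446,0.0583,<0.0001
rehosp,rpm,yes,0.0968,0.0307,0.0016
rehosp,age,>=75,-0.1822,0.0305,<0.0001
rehosp,nyha,III/IV,-0.1446,0.0355,<0.0001
rehosp,sex,female,-0.1257,0.0342,0.0002
rehosp,race,black,-0.2122,0.0596,0.0004
rehosp,race,hispanic,-0.1508,0.0762,0.0478
rehosp,race,other,0.0143,0.085,0.8663
rehosp,admission_reason,cardiac,-0.2144,0.0454,<0.0001
rehosp,admission_reason,noncardiac,-0.2108,0.0392,<0.0001
rehosp,admission_reason,unknown,-0.2999,0.0913,0.001
rehosp,chf_duration,<9mo,0.0171,0.0535,0.7494
rehosp,chf_duration,>9mo,-0.1339,0.0485,0.0057
rehosp,af_flutter,yes,-0.183,0.0312,<0.0001
rehosp,nidcm,<9mo,0.1899,0.057,0.0009
rehosp,nidcm,>9mo,0.1076,0.043,0.0123
rehosp,cabg_pci,yes,-0.0885,0.034,0.0093
rehosp,pacemaker,yes,-0.1441,0.0543,0.008
rehosp,cerebrovascular,yes,-0.127,0.0392,0.0012
rehosp,lung_disease,yes,-0.3403,0.0335,<0.0001
rehosp,diabetes,yes,-0.1414,0.031,<0.0001
rehosp,dialysis,yes,-0.2753,0.0921,0.0028
rehosp,ivc,lbbb,0.1806,0.0399,<0.0001
rehosp,ivc,rbbb,-0.0226,0.0576,0.6947
rehosp,ivc,paced,0.1374,0.0685,0.045
rehosp,ivc,other,-0.0421,0.0473,0.3726
rehosp,creatinine,1.5-2.5,-0.2105,0.0431,<0.0001
rehosp,creatinine,>2.5,-0.392,0.0879,<0.0001
rehosp,bun,20-40,-0.1701,0.0337,<0.0001
rehosp,bun,>40,-0.4382,0.0588,<0.0001
rehosp,sodium,<=135,-0.1765,0.0406,<0.0001
rehosp,sodium,>145,0.0376,0.1516,0.8043
rehosp,pop_density,>3000,-0.1302,0.0501,0.0094
death,(scale),,0.9875,0.0146,
death,(shape),,1.0127,0.015,
death,(intercept),,9.976,0.1219,<0.0001
death,rpm,yes,0.1666,0.0346,<0.0001
death,hospitalization,yes,-1.5451,0.0652,<0.0001
death,age,>=75,-0.3385,0.0339,<0.0001
death,nyha,III/IV,-0.2279,0.0438,<0.0001
death,sex,female,0.1613,0.0382,<0.0001
death,race,black,-0.1957,0.0597,0.001
death,race,hispanic,0.1268,0.0839,0.1307
death,race,other,-0.0258,0.0896,0.7733
death,admission_reason,cardiac,-0.2046,0.0433,<0.0001
death,admission_reason,noncardiac,-0.1265,0.0419,0.0026
death,admission_reason,unknown,-0.255,0.0812,0.0017
death,chf_hospitalization,<6mo,-0.2303,0.0385,<0.0001
death,chf_hospitalization,>6mo,-0.1616,0.043,0.0002
death,af_flutter,yes,-0.1895,0.033,<0.0001
death,nidcm,<9mo,0.1951,0.0651,0.0027
death,nidcm,>9mo,-0.0625,0.047,0.1834
death,cabg_pci,yes,-0.1427,0.0369,0.0001
death,pacemaker,yes,0.1533,0.0587,0.009
death,cerebrovascular,yes,-0.155,0.0399,0.0001
death,lung_disease,yes,-0.2539,0.0344,<0.0001
death,diabetes,yes,-0.1304,0.0334,<0.0001
death,hypertension,yes,0.0784,0.0418,0.0605
death,dialysis,yes,-0.1688,0.0783,0.0312
death,qrs,>120,0.1117,0.0447,0.0124
death,ivc,lbbb,-0.0131,0.0536,0.8066
death,ivc,rbbb,-0.1856,0.066,0.0049
death,ivc,paced,-0.0706,0.0789,0.3706
death,ivc,other,-0.1724,0.054,0.0014
death,creatinine,1.5-2.5,-0.1641,0.043,0.0001
death,creatinine,>2.5,-0.5601,0.075,<0.0001
death,bun,20-40,-0.3104,0.0402,<0.0001
death,bun,>40,-0.5614,0.0582,<0.0001
death,sodium,<=135,-0.289,0.0393,<0.0001
death,sodium,>145,-0.2652,0.1375,0.0538
death,sbp,100-130,0.1389,0.0607,0.0221
death,sbp,>130,0.2658,0.0617,<0.0001
death,icd_type,dual,0.1859,0.0605,0.0021
death,icd_type,biventricular,0.2123,0.0617,0.0006
death,teaching,teaching,-0.0483,0.045,0.2833
death,teaching,other,-0.13,0.0385,0.0007
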