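source,variable,level,group,count,printed_pct
table2,phenotype,Diverticulosis,Available,6556,80
table2,phenotype,Mild diverticulitis,Available,1337,16
table2,phenotype,Operative or recurrent,Available,335,4.1
table2,phenotype,Diverticulosis,Missing,5328,77
table2,phenotype,Mild diverticulitis,Missing,1170,17
table2,phenotype,Operative or recurrent,Missing,394,5.7
table2,income,Less than 50k,Available,2749,39
table2,income,50-100k,Available,1892,27
table2,income,More than 100k,Available,2351,34
table2,income,Less than 50k,Missing,2679,55
table2,income,50-100k,Missing,1110,23
table2,income,More than 100k,Missing,1077,22
table2,education,Less than high school,Available,460,5.7
table2,education,High school,Available,1058,13
table2,education,Some college or more,Available,6537,81
table2,education,Less than high school,Missing,836,13
table2,education,High school,Missing,1535,23
table2,education,Some college or more,Missing,4259,64
table3,income,Less than 50k,Control,6302,39
table3,income,50-100k,Control,4212,26
table3,income,More than 100k,Control,5834,36
table3,income,Less than 50k,Diverticulosis,2099,38
table3,income,50-100k,Diverticulosis,1523,27
table3,income,More than 100k,Diverticulosis,1959,35
table3,income,Less than 50k,Mild,528,46
table3,income,50-100k,Mild,299,26
table3,income,More than 100k,Mild,310,27
table3,income,Less than 50k,Severe,122,45
table3,income,50-100k,Severe,70,26
table3,income,More than 100k,Severe,82,30
table3,education,Less than high school,Control,853,4.6
table3,education,High school,Control,2365,13
table3,education,Some college or more,Control,15266,83
table3,education,Less than high school,Diverticulosis,357,5.6
table3,education,High school,Diverticulosis,783,12
table3,education,Some college or more,Diverticulosis,5284,82
table3,education,Less than high school,Mild,80,6.1
table3,education,High school,Mild,229,18
table3,education,Some college or more,Mild,995,76
table3,education,Less than high school,Severe,23,7.0
table3,education,High school,Severe,46,14
table3,education,Some college or more,Severe,258,79
table3,unmet_social_need,1,Control,7963,42
table3,unmet_social_need,0,Control,11009,
table3,unmet_social_need,1,Diverticulosis,2480,38
table3,unmet_social_need,0,Diverticulosis,4076,
table3,unmet_social_need,1,Mild,606,45
table3,unmet_social_need,0,Mild,731,
table3,unmet_social_need,1,Severe,168,50
table3,unmet_social_need,0,Severe,167,
quintile,severe_case,1,Q5,74,5
quintile,severe_case,0,Q5,1406,
quintile,severe_case,1,Q1,73,4
quintile,severe_case,0,Q1,1752,
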