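"clinic_id","question_id","yes_count","n"
"insel","Q1.1",2,5
"acqua","Q1.1",3,5
"ukl","Q1.1",3,5
"insel","Q1.2",2,5
"acqua","Q1.2",1,5
"ukl","Q1.2",1,5
"insel","Q1.3",2,5
"acqua","Q1.3",1,5
"ukl","Q1.3",1,5
"insel","Q1.4",2,5
"acqua","Q1.4",0,5
"ukl","Q1.4",1,5
"insel","Q2.1",2,5
"acqua","Q2.1",1,5
"ukl","Q2.1",2,5
"insel","Q2.2",1,5
"acqua","Q2.2",1,5
"ukl","Q2.2",2,5
"insel","Q2.3",1,5
"acqua","Q2.3",0,5
"ukl","Q2.3",2,5
"insel","Q2.4",1,5
"acqua","Q2.4",0,5
"ukl","Q2.4",2,5
"insel","Q3",2,5
"acqua","Q3",1,5
"ukl","Q3",4,5
"insel","Q4",4,5
"acqua","Q4",2,5
"ukl","Q4",5,5
"insel","Q5",4,5
"acqua","Q5",2,5
"ukl","Q5",5,5
"insel","Q6.1",1,5
"acqua","Q6.1",1,5
"ukl","Q6.1",3,5
"insel","Q6.2",0,5
"acqua","Q6.2",0,5
"ukl","Q6.2",0,5
"insel","Q6.3",4,5
"acqua","Q6.3",5,5
"ukl","Q6.3",5,5
"insel","Q6.4",3,5
"acqua","Q6.4",3,5
"ukl","Q6.4",4,5
"insel","Q6.5",3,5
"acqua","Q6.5",1,5
"ukl","Q6.5",1,5
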