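"question_id","text","depends_on"
"Q1.1","A general table-setup standard exists in the team",""
"Q1.2","Knows who made the general standard","Q1.1"
"Q1.3","The general standard is written down","Q1.1;Q1.2"
"Q1.4","Has access to the written general standard","Q1.1;Q1.2;Q1.3"
"Q2.1","A FESS-specific table-setup standard exists in the team",""
"Q2.2","Knows who made the FESS standard","Q2.1"
"Q2.3","The FESS standard is written down","Q2.1;Q2.2"
"Q2.4","Has access to the written FESS standard","Q2.1;Q2.2;Q2.3"
"Q3","Knows literature describing table setup for an operation",""
"Q4","Would support a written per-operation setup standard",""
"Q5","A written standard could help trainees and new entrants",""
"Q6.1","Influence: the individual surgeon",""
"Q6.2","Influence: chance / daily mood",""
"Q6.3","Influence: personal preference",""
"Q6.4","Influence: own training",""
"Q6.5","Influence: the in-house standard",""
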