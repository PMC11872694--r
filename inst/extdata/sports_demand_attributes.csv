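attribute,wording,dimension,dimension_name
A1,Surveillance sites into community services,A,Physical monitoring services
A2,Provide physical fitness monitoring services,A,Physical monitoring services
A3,Provide exercise prescription design,A,Physical monitoring services
B1,Offer sports competitions,B,Sports activities services
B2,Equipment conditions of the surrounding sites,B,Sports activities services
C1,Provide physical activity information,C,Sports information services
C2,Physical activity information,C,Sports information services
C3,Sports travel information,C,Sports information services
C4,Provide health and fitness knowledge,C,Sports information services
C5,National and local sports policies and regulations,C,Sports information services
D1,Fitness pathways,D,Fitness facility services
D2,Open space,D,Fitness facility services
D3,Fitness equipment,D,Fitness facility services
D4,The track and field,D,Fitness facility services
D5,"Various courts (basket, foot, goalball, etc.)",D,Fitness facility services
E1,Motor skills training,E,Fitness guidance services
E2,Explain sports rules,E,Fitness guidance services
E3,Health education,E,Fitness guidance services
E4,Scientific fitness guidance,E,Fitness guidance services
F1,Official sports organizations,F,Fitness organization services
F2,Grassroots sports organizations,F,Fitness organization services
F3,Organize an exercise routine,F,Fitness organization services
F4,Organize and participate in sports activities (events),F,Fitness organization services
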