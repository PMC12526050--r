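item_id,text,pct_patients,pct_proxies,pct_hcps,n_patients,n_proxies,n_hcps
1,"Change in consciousness (ie, alertness, awareness)?",54.0,52.1,96.9,113,71,65
2,Problems with your orientation?,44.6,45.1,100.0,112,71,64
3,"Change in your behavior/personality (eg, inappropriate language or lack of empathy)?",40.7,45.7,100.0,113,70,64
4,Lack of energy?,80.4,47.9,100.0,112,71,65
5,Lack of motivation?,59.8,47.9,98.5,112,71,65
6,Lack of appetite,32.1,29.0,98.5,112,69,65
8,"Problems sleeping (eg, amount or quality of sleep)?",60.4,62.9,96.9,111,70,65
9,Difficulty concentrating?,76.6,72.9,96.9,111,70,64
10,Difficulty remembering things?,78.4,72.7,100.0,111,70,63
13,"Problems controlling your emotions (eg, control of anger)?",45.0,38.8,96.8,111,68,63
14,"Change in your emotions (eg, more or less anxiety or anger)?",54.6,50.0,98.4,108,68,63
15,"Problems thinking (eg, thinking slowly or having uncontrollable thoughts)?",52.3,49.3,100.0,109,64,64
16,"Problems with organization and planning (eg, organizing a dinner)?",51.4,57.4,100.0,111,68,64
17,Problems managing your time?,42.3,39.7,96.8,110,68,63
18,"Problems switching between thoughts (eg, when problem-solving)?",52.3,55.9,95.3,109,68,64
19,Lack of insight into your behavior?,28.2,41.8,95.3,110,67,64
21,Difficulty solving problems?,46.8,41.8,100.0,111,67,64
23,"Problems expressing language (ie, spoken or written messages, or sign or body language)?",33.3,29.9,100.0,111,67,64
29,"Any other problems with the eyes (eg, tired, dry, or itchy eyes)?",41.6,33.8,80.0,113,71,60
30,Problems with hearing?,39.1,47.7,81.9,110,65,60
32,Problems maintaining balance while standing or moving?,49.1,27.5,98.3,110,69,60
33,Dizziness?,37.3,27.5,98.3,110,70,60
37,Change in sensitivity to temperature?,26.1,32.4,61.7,111,67,60
41,"Pain in one body part (eg, headache or back pain)?",52.7,39.7,95.5,110,68,60
42,"Pain in multiple body parts (eg, headache and back pain)?",33.9,32.8,88.3,109,67,60
43,Radiating pain in a specific region?,33.0,28.4,81.7,109,67,60
45,"Problems with speech (eg, tempo, slurring words, stuttering, or articulating)?",34.8,31.0,100.0,112,71,59
54,"Reduced tolerance to physical exercise (eg, feeling out of breath or more easily fatigued)?",53.2,56.9,94.9,111,64,59
61,"Problems with bowel movements (eg, change in consistency or frequency of bowel movements)?",43.1,33.3,87.5,109,66,56
62,Problems maintaining your body weight?,43.6,37.3,80.4,110,67,56
67,Constantly feeling too hot or too cold?,31.8,28.1,50.9,110,64,55
68,"Problems with urination (eg, changes in frequency or incontinence)?",37.8,31.4,92.7,112,70,55
70,"Problems with sexual activity (eg, change in sexual interest or trouble reaching an orgasm)?",42.7,50.7,89.1,110,69,55
74,"Problems with your joints (eg, ease of movement or dislocation)?",33.0,27.1,74.5,112,70,55
76,Tension in muscles?,35.5,33.8,80.0,110,68,55
79,"Distorted walking pattern (eg, swaying or stiff walking pattern)?",33.9,26.5,98.2,109,68,55
80,Sensation of muscle stiffness?,29.1,27.9,72.7,110,68,55
81,"Problems with your skin (eg, change in pigmentation, sensitivity to sunlight, or more sweating than usual)?",25.0,28.2,65.5,112,71,55
82,"Unpleasant sensations of the skin (eg, itching, burning, or tingling)?",32.7,28.6,72.7,110,70,55
83,"Problems with your hair (eg, change in growth, color, or location of hair)?",35.1,32.4,74.5,111,71,55
91,"Problems obtaining new information (eg, asking for facts or names of people)?",44.9,31.3,98.2,107,67,55
97,"Problems learning new skills (eg, playing a new game)?",33.0,29.7,94.5,106,64,55
98,Problems making decisions?,49.1,40.9,100.0,108,66,55
100,Problems doing several different things at the same time?,62.8,60.3,100.0,113,68,55
101,Problems functioning independently in daily life?,33.6,32.4,100.0,113,68,54
103,Problems handling stress?,61.8,60.9,98.2,110,69,55
104,"Problems having a conversation (eg, starting, continuing, or ending a conversation with one person or many people)?",33.3,28.6,100.0,114,70,54
105,"Problems having a discussion (eg, starting, continuing, or ending a discussion with one person or many people)?",39.8,34.3,98.1,113,70,54
106,"Problems using communication devices (eg, telephone or computer)?",30.1,26.5,96.3,113,68,54
107,"Difficulty changing your body position (eg, lying down, sitting down, or standing up)?",37.7,27.9,96.2,114,68,52
116,"Difficulty moving around by means other than walking (eg, climbing stairs, swimming, or running)?",36.4,29.7,96.1,107,64,51
119,"Problems driving a vehicle (eg, a car or bicycle)?",33.0,41.3,94.3,106,63,53
142,Problems engaging in paid work?,36.8,33.3,92.3,106,63,52
144,Problems doing your personal finances?,27.0,31.8,92.2,111,66,51
145,"Problems participating in community activities (eg, clubs or organizations)?",30.9,26.9,88.2,110,67,51
146,"Problems participating in recreation and leisure activities (eg, sports or hobbies)?",31.5,33.3,87.2,111,69,51
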