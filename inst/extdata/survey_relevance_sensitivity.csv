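item_id,text,pct_patients,pct_proxies,pct_hcps,n_patients,n_proxies,n_hcps
1,"Change in consciousness (ie, alertness, awareness)?",19.6,14.1,76.9,113,71,65
2,Problems with your orientation?,15.2,11.3,79.7,112,71,64
3,"Change in your behavior/personality (eg, inappropriate language or lack of empathy)?",8.8,18.6,85.9,113,70,64
4,Lack of energy?,34.8,43.7,83.1,112,71,65
5,Lack of motivation?,26.8,25.4,66.2,112,71,65
6,Lack of appetite,15.2,14.5,36.9,112,69,65
8,"Problems sleeping (eg, amount or quality of sleep)?",25.2,20.0,72.3,111,70,65
9,Difficulty concentrating?,33.3,40.6,87.5,111,70,64
10,Difficulty remembering things?,36.0,40.0,88.9,111,70,63
13,"Problems controlling your emotions (eg, control of anger)?",11.7,5.9,63.5,111,68,63
14,"Change in your emotions (eg, more or less anxiety or anger)?",15.7,20.6,66.7,108,68,63
15,"Problems thinking (eg, thinking slowly or having uncontrollable thoughts)?",18.3,20.3,76.8,109,64,64
16,"Problems with organization and planning (eg, organizing a dinner)?",20.7,29.4,75.0,111,68,64
17,Problems managing your time?,15.5,16.2,50.8,110,68,63
18,"Problems switching between thoughts (eg, when problem-solving)?",16.5,17.6,60.9,109,68,64
19,Lack of insight into your behavior?,4.5,16.4,57.9,110,67,64
21,Difficulty solving problems?,9.0,10.4,71.9,111,67,64
23,"Problems expressing language (ie, spoken or written messages, or sign or body language)?",9.0,7.5,78.1,111,67,64
29,"Any other problems with the eyes (eg, tired, dry, or itchy eyes)?",9.7,8.5,28.3,113,71,60
30,Problems with hearing?,10.9,20.0,36.7,110,65,60
32,Problems maintaining balance while standing or moving?,20.0,14.3,70.0,110,69,60
33,Dizziness?,10.0,2.9,63.3,110,70,60
37,Change in sensitivity to temperature?,11.7,14.7,21.7,111,67,60
41,"Pain in one body part (eg, headache or back pain)?",15.5,17.6,75.0,110,68,60
42,"Pain in multiple body parts (eg, headache and back pain)?",11.9,13.4,45.0,109,67,60
43,Radiating pain in a specific region?,4.6,6.0,48.3,109,67,60
45,"Problems with speech (eg, tempo, slurring words, stuttering, or articulating)?",10.7,8.5,78.0,112,71,59
54,"Reduced tolerance to physical exercise (eg, feeling out of breath or more easily fatigued)?",26.1,17.2,66.1,111,64,59
61,"Problems with bowel movements (eg, change in consistency or frequency of bowel movements)?",14.7,13.6,51.8,109,66,56
62,Problems maintaining your body weight?,12.7,14.9,41.1,110,67,56
67,Constantly feeling too hot or too cold?,10.9,12.5,16.4,110,64,55
68,"Problems with urination (eg, changes in frequency or incontinence)?",12.5,12.9,43.6,112,70,55
70,"Problems with sexual activity (eg, change in sexual interest or trouble reaching an orgasm)?",21.8,33.3,40.0,110,69,55
74,"Problems with your joints (eg, ease of movement or dislocation)?",13.4,12.9,32.7,112,70,55
76,Tension in muscles?,13.6,7.4,27.3,110,68,55
79,"Distorted walking pattern (eg, swaying or stiff walking pattern)?",11.9,8.8,69.1,109,68,55
80,Sensation of muscle stiffness?,10.0,7.4,36.4,110,68,55
81,"Problems with your skin (eg, change in pigmentation, sensitivity to sunlight, or more sweating than usual)?",4.5,4.2,14.5,112,71,55
82,"Unpleasant sensations of the skin (eg, itching, burning, or tingling)?",11.8,2.9,23.6,110,70,55
83,"Problems with your hair (eg, change in growth, color, or location of hair)?",4.5,9.9,34.5,111,71,55
91,"Problems obtaining new information (eg, asking for facts or names of people)?",11.2,4.5,69.1,107,67,55
97,"Problems learning new skills (eg, playing a new game)?",12.3,6.3,43.6,106,64,55
98,Problems making decisions?,20.4,16.7,76.4,108,66,55
100,Problems doing several different things at the same time?,9.7,25.0,78.2,113,68,55
101,Problems functioning independently in daily life?,11.9,8.8,87.0,113,68,54
103,Problems handling stress?,28.2,20.3,72.7,110,69,55
104,"Problems having a conversation (eg, starting, continuing, or ending a conversation with one person or many people)?",14.9,7.1,61.1,114,70,54
105,"Problems having a discussion (eg, starting, continuing, or ending a discussion with one person or many people)?",18.6,10.0,66.7,113,70,54
106,"Problems using communication devices (eg, telephone or computer)?",7.1,2.9,57.4,113,68,54
107,"Difficulty changing your body position (eg, lying down, sitting down, or standing up)?",11.4,7.4,51.9,114,68,52
116,"Difficulty moving around by means other than walking (eg, climbing stairs, swimming, or running)?",17.8,10.9,68.6,53,64,51
119,"Problems driving a vehicle (eg, a car or bicycle)?",22.6,25.4,73.6,106,63,53
142,Problems engaging in paid work?,20.3,22.2,80.8,106,63,52
144,Problems doing your personal finances?,9.0,15.2,66.7,111,66,51
145,"Problems participating in community activities (eg, clubs or organizations)?",13.6,13.4,51.0,110,67,51
146,"Problems participating in recreation and leisure activities (eg, sports or hobbies)?",14.4,15.9,48.9,111,69,51
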