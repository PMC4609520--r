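no,name,size,ensemble_mean,ensemble_sd,mvknn_mean,mvknn_sd,cnn_mean,cnn_sd
1,Arthralgia syndrome,481,82.4,2.7,83.1,2.8,84.2,3.4
2,Acne,75,90.2,2.1,86.4,2.3,85.3,3.1
3,Epilepsy,26,89.1,2.5,88.0,1.9,86.9,2.4
4,Tinnitus and deafness,68,83.1,2.6,81.0,3.1,85.2,3.6
5,Abdominal pain,96,84.7,2.7,81.3,2.9,82.8,3.4
6,Allergic rhinitis,376,89.2,2.1,84.1,2.8,85.3,3.0
7,Neck and shoulder pain,110,91.4,1.9,88.4,2.1,86.0,2.5
8,Cervical spondylosis,33,92.6,2.2,87.7,2.9,90.5,3.1
9,Cough,96,88.5,2.7,86.9,3.1,87.1,3.9
10,Facial paralysis,89,82.7,1.3,78.8,2.5,79.1,3.0
11,Traumatic brain injury,47,85.8,2.1,86.0,2.9,85.1,2.6
12,Migraine,33,93.0,2.9,88.7,3.2,89.4,3.6
13,Ankylosing spondylitis,33,91.9,2.0,90.0,3.6,91.1,3.9
14,Insomnia,47,90.2,2.2,84.5,3.3,88.5,3.6
15,Headache,145,86.6,2.5,87.1,3.2,89.2,3.8
16,Flaccidity syndrome,124,87.2,1.9,83.1,2.8,84.4,3.1
17,Stomachache,145,89.2,2.4,86.5,2.8,87.2,3.1
18,Asthma,355,90.6,2.1,88.2,2.9,88.6,2.9
19,Palpitation,33,90.2,2.5,89.9,3.1,86.5,3.4
20,Lumbocrural pain,397,88.1,2.3,82.1,3.2,87.2,3.8
21,Urticaria and rubella,26,85.4,2.3,84.2,3.1,84.9,3.0
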