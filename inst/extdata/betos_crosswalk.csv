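hcpcs,betos_category
99202,evaluation_management
99203,evaluation_management
99204,evaluation_management
99211,evaluation_management
99212,evaluation_management
99213,evaluation_management
99214,evaluation_management
99215,evaluation_management
99385,evaluation_management
99395,evaluation_management
10060,procedures
11042,procedures
17110,procedures
20610,procedures
29881,procedures
43239,procedures
45380,procedures
47562,procedures
49505,procedures
66984,procedures
92250,procedures
S0625,procedures
71045,imaging
71046,imaging
73030,imaging
73562,imaging
70450,imaging
71250,imaging
74177,imaging
70551,imaging
72148,imaging
73721,imaging
76700,imaging
76805,imaging
93306,imaging
77067,imaging
77063,imaging
78452,imaging
80048,test
80053,test
80061,test
82947,test
83036,test
83037,test
83721,test
84443,test
85025,test
87086,test
36415,test
E0601,durable_medical_equipment
E1390,durable_medical_equipment
K0001,durable_medical_equipment
L1833,durable_medical_equipment
A4253,durable_medical_equipment
A0428,other
97110,other
97140,other
92014,other
G0008,other
90471,other
90686,other
C1713,unclassified
C1776,unclassified
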