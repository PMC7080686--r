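revenue_code,betos_category
0120,other
0250,other
0270,durable_medical_equipment
0300,test
0301,test
0305,test
0320,imaging
0350,imaging
0360,unclassified
0402,imaging
0403,imaging
0450,evaluation_management
0490,procedures
0510,evaluation_management
0610,imaging
0710,unclassified
0940,other
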