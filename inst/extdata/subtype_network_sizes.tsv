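phenotype	nodes	edges
LuminalA	1451	9941
LuminalB	1018	9898
Basal	1046	9966
HER2	2100	9856
NonTumor	1027	9894
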