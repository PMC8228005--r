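14	40000000	42000000	QTL_blood_1	health/blood parameters
14	74000000	75000000	QTL_fatness_1	meat and carcass/fatness
5	62000000	63000000	QTL_blood_2	health/blood parameters
13	177000000	179500000	QTL_conformation_1	exterior/conformation
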