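gene	category
CDH23	cadherin signaling pathway
MSI1	Wnt signaling pathway
MSI2	Notch signaling pathway
NUMB	Notch signaling pathway
DNER	Notch signaling pathway
SCN10A	nicotinic acetylcholine receptor signaling pathway
SCN11A	nicotinic acetylcholine receptor signaling pathway
ROBO2	axon guidance
NAV2	axon guidance
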