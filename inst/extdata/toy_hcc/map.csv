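code,cc
DM1,CC_DIAB
DM2,CC_DIAB
DMC,CC_DIAB_COMP
NEO,CC_CANCER
LYMPH,CC_CANCER
METS,CC_METS
CAD,CC_CAD
MI,CC_CAD
CHF,CC_CHF
DEP,CC_PSYCH
SCZ,CC_PSYCH
BIP,CC_PSYCH
COPD,CC_LUNG
ASTH,CC_LUNG
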