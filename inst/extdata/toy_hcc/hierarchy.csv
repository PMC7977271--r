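dominant_cc,suppressed_cc
CC_DIAB_COMP,CC_DIAB
CC_METS,CC_CANCER
CC_CHF,CC_CAD
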