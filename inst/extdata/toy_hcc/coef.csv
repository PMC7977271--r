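kind,key1,key2,weight
cc,CC_DIAB,,0.195
cc,CC_DIAB_COMP,,0.325
cc,CC_CANCER,,0.293
cc,CC_METS,,0.617
cc,CC_CAD,,0.162
cc,CC_CHF,,0.26
cc,CC_PSYCH,,0.162
cc,CC_LUNG,,0.215
demo,F,0-30,0.05
demo,F,30-35,0.05
demo,F,35-40,0.05
demo,F,40-45,0.1125
demo,F,45-50,0.2175
demo,F,50-55,0.3225
demo,F,55-60,0.4275
demo,F,60-65,0.5325
demo,F,65-70,0.6375
demo,F,70-75,0.7425
demo,F,75-80,0.8475
demo,F,80-85,0.9525
demo,F,85-90,1.0575
demo,F,90-Inf,1.1625
demo,M,0-30,0.05
demo,M,30-35,0.05
demo,M,35-40,0.05
demo,M,40-45,0.0825
demo,M,45-50,0.1875
demo,M,50-55,0.2925
demo,M,55-60,0.3975
demo,M,60-65,0.5025
demo,M,65-70,0.6075
demo,M,70-75,0.7125
demo,M,75-80,0.8175
demo,M,80-85,0.9225
demo,M,85-90,1.0275
demo,M,90-Inf,1.1325
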