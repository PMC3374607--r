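variable,p
nod2,0.003
atg16l1,0.006
gender,0.130
race,0.316
age,0.001
smoker,0.003
cdiff,0.001
bmi,0.006
asa5,0.001
steroids,0.001
immunomodulators,0.001
anti_tnf,0.001
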