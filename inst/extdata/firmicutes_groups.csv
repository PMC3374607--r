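name,category
clostridium group iv,Firmicutes_ClostridiumIV
clostridium iv,Firmicutes_ClostridiumIV
clostridium cluster iv,Firmicutes_ClostridiumIV
clostridiales incertae sedis iv,Firmicutes_ClostridiumIV
ruminococcaceae,Firmicutes_ClostridiumIV
faecalibacterium,Firmicutes_ClostridiumIV
ruminococcus,Firmicutes_ClostridiumIV
clostridium group xiva,Firmicutes_ClostridiumXIVa
clostridium xiva,Firmicutes_ClostridiumXIVa
clostridium cluster xiva,Firmicutes_ClostridiumXIVa
lachnospiraceae,Firmicutes_ClostridiumXIVa
roseburia,Firmicutes_ClostridiumXIVa
blautia,Firmicutes_ClostridiumXIVa
coprococcus,Firmicutes_ClostridiumXIVa
dorea,Firmicutes_ClostridiumXIVa
eubacterium rectale,Firmicutes_ClostridiumXIVa
bacillus,Firmicutes_Bacillus
bacilli,Firmicutes_Bacillus
lactobacillales,Firmicutes_Bacillus
lactobacillus,Firmicutes_Bacillus
streptococcus,Firmicutes_Bacillus
enterococcus,Firmicutes_Bacillus
staphylococcus,Firmicutes_Bacillus
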