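name,category,drug_classes,maintenance_flag,event
7+3,Intensive,cytarabine;anthracycline,FALSE,
7+3-midostaurin,Intensive,cytarabine;anthracycline;midostaurin,FALSE,
AZA-VEN,HMA,azacitidine;venetoclax,FALSE,
AZA-mono,HMA,azacitidine,FALSE,
Gilteritinib,Targeted,gilteritinib,FALSE,
Hydroxycarbamide,Cytoreduction,hydroxycarbamide,FALSE,
Auto-SCT,HSCT,,FALSE,auto
Allo-SCT,HSCT,,FALSE,allo
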