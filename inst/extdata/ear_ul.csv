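nutrient,life_stage,status,ear,ul,ul_basis,units,source
zinc,child_1_3y,none,3.6,7,total,mg_d,EAR low-bioavailability set; UL IOM (not printed in modelling source)
zinc,woman_15_49y,none,9.9,40,total,mg_d,EAR low end of WRA range; UL IOM
zinc,woman_15_49y,pregnant,13.7,40,total,mg_d,EAR high end of WRA range; UL IOM
zinc,woman_15_49y,lactating,11.8,40,total,mg_d,EAR intermediate in WRA range (configurable); UL IOM
zinc,man_19_45y,none,12.7,40,total,mg_d,EAR adult men; UL IOM
folate,child_1_3y,none,120,300,fortificant,ug_dfe_d,EAR dietary folate; UL IOM folic acid (fortificant only)
folate,woman_15_49y,none,320,1000,fortificant,ug_dfe_d,EAR low end of WRA range; UL IOM folic acid
folate,woman_15_49y,pregnant,520,1000,fortificant,ug_dfe_d,EAR high end of WRA range; UL IOM folic acid
folate,woman_15_49y,lactating,450,1000,fortificant,ug_dfe_d,EAR IOM lactation (within WRA range); UL IOM folic acid
folate,man_19_45y,none,320,1000,fortificant,ug_dfe_d,EAR adult men; UL IOM folic acid
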