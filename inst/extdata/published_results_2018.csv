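factor_name,category,n_orgs_mentioning,pct_orgs_mentioning,total_mentions,nci_mentions,acs_mentions
Exercise,other,60,74,2796,96,340
Family history,other,54,67,1167,249,74
Diet,other,48,59,1514,28,172
Genetics,other,42,52,1257,140,67
Alcohol,other,39,48,722,34,69
Breast density,other,36,44,542,171,66
Body weight,other,29,36,456,21,77
Hormone replacement therapy,other,24,30,800,37,100
Pesticides,specific_environmental,24,30,565,2,1
Bisphenols,specific_environmental,20,25,1582,0,0
Contamination,general_environmental,20,25,517,9,0
Pollution,general_environmental,20,25,644,0,1
Birth control,other,19,23,398,32,27
Parabens,specific_environmental,19,23,419,0,25
Endocrine disrupting chemicals,specific_environmental,17,21,382,0,1
Phthalates,specific_environmental,14,17,546,0,0
Diethylstilbestrol,other,13,16,253,2,5
The precautionary principle,general_environmental,12,15,142,0,0
Flame retardants,specific_environmental,10,12,1074,0,0
Air pollution,specific_environmental,9,11,80,0,0
Polycyclic aromatic hydrocarbons,specific_environmental,9,11,104,0,0
PFAS,specific_environmental,9,11,230,0,0
Oxybenzone,specific_environmental,6,7,18,0,0
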