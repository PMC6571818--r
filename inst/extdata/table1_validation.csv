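name,rt,not_in_blank,above_noise,good_peak_shape,isotopic_match,chemspider_matches,extractables_matches,msms
"2,3,6-Trimethylphenol",16.70,TRUE,TRUE,TRUE,[M+H-H2O],50,5,no match
3-Methoxybenzaldehyde,11.49,TRUE,TRUE,TRUE,[M+H],50,5,"3 or 4 methoxybenzaldehyde, 82%"
4-Methoxybenzaldehyde,12.99,TRUE,TRUE,TRUE,[M+H],50,5,"3 or 4 methoxybenzaldehyde, 82%"
8-Hydroxyquinoline,7.95,TRUE,TRUE,TRUE,[M+H],4,1,no MS/MS
Bensulfuron-methyl,1.70,TRUE,TRUE,TRUE,[M+H],50,1,no MS/MS
benzaldehyde,23.12,TRUE,TRUE,TRUE,[M+H],9,1,no MS/MS
Cinnamaldehyde,13.97,TRUE,TRUE,TRUE,[M+H],50,0,no MS/MS
Coumarin,17.63,TRUE,TRUE,TRUE,[M+H],32,0,80%
Erythorbic acid,2.10,TRUE,TRUE,TRUE,[M+H],27,0,no MS/MS
Diphenylamine,42.50,FALSE,TRUE,TRUE,[M+H],50,2,no MS/MS
Ethyl benzoate,19.65,TRUE,TRUE,TRUE,[M+H],50,1,no MS/MS
Ethyl cinnamate,21.71,TRUE,TRUE,TRUE,[M+H],50,0,"Benzyl Methacrylate, 61%"
Gallic acid,13.15,TRUE,TRUE,TRUE,[M+H-H2O],16,0,no MS/MS
Indole,7.95,TRUE,TRUE,TRUE,[M+H],42,0,no MS/MS
L-Glutamic acid,1.74,TRUE,TRUE,TRUE,[M+H],50,0,99.40%
L-Histidine,1.59,TRUE,TRUE,TRUE,[M+H],49,1,no MS/MS
L-Isoleucine,2.56,TRUE,TRUE,TRUE,[M+H],50,2,no MS/MS
L-Methionine,1.75,TRUE,TRUE,TRUE,[M+H],40,1,no match
L-Phenylalanine,4.02,TRUE,TRUE,TRUE,[M+H],50,1,99.60%
L-Proline,1.80,TRUE,TRUE,TRUE,[M+H],50,0,no MS/MS
L-Tyrosine,13.37,TRUE,TRUE,TRUE,[M+H],50,1,no MS/MS
Naringin dihydrochalcone,22.78,TRUE,TRUE,TRUE,[M+Na],0,0,no match
Nicotinamide,2.12,TRUE,TRUE,TRUE,[M+H],49,0,no MS/MS
Propyl gallate,8.56,TRUE,TRUE,TRUE,[M+H],49,1,no MS/MS
salicylic acid,15.77,TRUE,TRUE,TRUE,[M+H],39,1,no MS/MS
Tentoxin,19.06,TRUE,TRUE,TRUE,none,6,0,no match
Terephthalic acid,9.71,TRUE,TRUE,TRUE,[M+H],40,3,no MS/MS
Triphenylphosphine oxide,34.86,FALSE,TRUE,TRUE,[M+H],10,1,no MS/MS
Thidiazuron,1.92,TRUE,TRUE,TRUE,[M+H],31,1,no MS/MS
Trichlorfon,1.51,TRUE,TRUE,TRUE,[M+H],2,1,no MS/MS
Vanillin,16.17,TRUE,TRUE,TRUE,[M+H],50,2,no MS/MS
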