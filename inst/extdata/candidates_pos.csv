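name,formula,rt,polarity
"2,3,6-Trimethylphenol",C9H12O,16.70,pos
3-Methoxybenzaldehyde,C8H8O2,11.49,pos
4-Methoxybenzaldehyde,C8H8O2,12.99,pos
8-Hydroxyquinoline,C9H7NO,7.95,pos
Bensulfuron-methyl,C16H18N4O7S,1.70,pos
benzaldehyde,C7H6O,23.12,pos
Cinnamaldehyde,C9H8O,13.97,pos
Coumarin,C9H6O2,17.63,pos
Erythorbic acid,C6H8O6,2.10,pos
Diphenylamine,C12H11N,42.50,pos
Ethyl benzoate,C9H10O2,19.65,pos
Ethyl cinnamate,C11H12O2,21.71,pos
Gallic acid,C7H6O5,13.15,pos
Indole,C8H7N,7.95,pos
L-Glutamic acid,C5H9NO4,1.74,pos
L-Histidine,C6H9N3O2,1.59,pos
L-Isoleucine,C6H13NO2,2.56,pos
L-Methionine,C5H11NO2S,1.75,pos
L-Phenylalanine,C9H11NO2,4.02,pos
L-Proline,C5H9NO2,1.80,pos
L-Tyrosine,C9H11NO3,13.37,pos
Naringin dihydrochalcone,C27H34O14,22.78,pos
Nicotinamide,C6H6N2O,2.12,pos
Propyl gallate,C10H12O5,8.56,pos
salicylic acid,C7H6O3,15.77,pos
Tentoxin,C22H30N4O4,19.06,pos
Terephthalic acid,C8H6O4,9.71,pos
Triphenylphosphine oxide,,34.86,pos
Thidiazuron,C9H8N4OS,1.92,pos
Trichlorfon,,1.51,pos
Vanillin,C8H8O3,16.17,pos
Sucrose,C12H22O11,1.20,pos
Trehalose,C12H22O11,1.25,pos
Raffinose,C18H32O16,1.10,pos
Rutin,C27H30O16,14.80,pos
Catechin,C15H14O6,9.90,pos
Epicatechin,C15H14O6,10.60,pos
Maltol,C6H6O3,6.40,pos
Abscisic acid,C15H20O4,18.20,pos
Beta-carotene,C40H56,28.90,pos
Chlorophyllide a,,24.40,pos
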