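canonical_name,synonyms,formula,hazard_note
"2,3,6-Trimethylphenol",,C9H12O,irritant phenol
3-Methoxybenzaldehyde,m-anisaldehyde,C8H8O2,fragrance compound; may cause respiratory tract irritation
4-Methoxybenzaldehyde,p-anisaldehyde|anisaldehyde,C8H8O2,fragrance compound; may cause respiratory tract irritation
8-Hydroxyquinoline,oxine,C9H7NO,antiseptic; harmful if swallowed
Bensulfuron-methyl,,C16H18N4O7S,sulfonylurea herbicide
Benzaldehyde,benzenecarbaldehyde,C7H6O,harmful in quantity; CNS depressant at high dose
Cinnamaldehyde,cinnamic aldehyde,C9H8O,skin sensitizer
Coumarin,2H-chromen-2-one|1-benzopyran-2-one,C9H6O2,hepatotoxic; banned as direct food additive; EC limit 2 mg/kg food/day from naturals
Erythorbic acid,isoascorbic acid|D-araboascorbic acid,C6H8O6,large doses may cause gastrointestinal upset
Diphenylamine,N-phenylaniline,C12H11N,post-harvest fungicide; suspected toxicant
Ethyl benzoate,,C9H10O2,irritant ester
Ethyl cinnamate,,C11H12O2,flavouring; irritant at high dose
Gallic acid,"3,4,5-trihydroxybenzoic acid",C7H6O5,pro-oxidant at high dose
Indole,2-3-benzopyrrole,C8H7N,harmful if swallowed
L-Glutamic acid,glutamate|L-glutamate,C5H9NO4,monosodium glutamate symptom complex in sensitive individuals
L-Histidine,,C6H9N3O2,excess intake may affect copper status
L-Isoleucine,,C6H13NO2,branched-chain amino acid; excess burdens metabolism
L-Methionine,,C5H11NO2S,excess intake raises homocysteine
L-Phenylalanine,,C9H11NO2,contraindicated in phenylketonuria
L-Proline,,C5H9NO2,excess intake poorly characterized
L-Tyrosine,,C9H11NO3,interacts with MAOI medication
Naringin dihydrochalcone,,C27H34O14,intense sweetener; limited toxicology
Nicotinamide,niacinamide|vitamin B3 amide,C6H6N2O,hepatotoxic at gram doses
Propyl gallate,propyl 3-4-5-trihydroxybenzoate,C10H12O5,antioxidant additive; possible endocrine activity
Salicylic acid,2-hydroxybenzoic acid,C7H6O3,salicylism at high dose
Tentoxin,,C22H30N4O4,phytotoxic cyclic tetrapeptide
Terephthalic acid,"1,4-benzenedicarboxylic acid",C8H6O4,urolithiasis in rodents at high dose
Triphenylphosphine oxide,TPPO,,suspected leachable; harmful if swallowed
Thidiazuron,,C9H8N4OS,plant growth regulator; harmful to aquatic life
Trichlorfon,metrifonate,,organophosphate insecticide; cholinesterase inhibitor
Vanillin,4-hydroxy-3-methoxybenzaldehyde,C8H8O3,large doses may cause headache
Citric acid,2-hydroxypropane-1-2-3-tricarboxylic acid,C6H8O7,dental erosion and irritation in abundance or if inhaled
L-Aspartic acid,aspartate,C4H7NO4,excitotoxic only in abundance
Naringin,naringenin 7-O-neohesperidoside,C27H32O14,grapefruit flavonoid; risk only in abundance or by inhalation
Succinic acid,butanedioic acid,C4H6O4,irritant in concentrated form
Atropine,,C17H23NO3,anticholinergic alkaloid; highly toxic
Strychnine,,C21H22N2O2,convulsant alkaloid; highly toxic
Caffeine,"1,3,7-trimethylxanthine",C8H10N4O2,cardiovascular effects at high dose
Nicotine,,C10H14N2,highly toxic alkaloid
Solanine,,C45H73NO15,glycoalkaloid; gastrointestinal and neurological toxin
Amygdalin,,C20H27NO11,cyanogenic glycoside
Ricinine,,C8H8N2O2,toxic alkaloid of castor bean
Colchicine,,C22H25NO6,mitotic poison; narrow therapeutic index
Aflatoxin B1,,C17H12O6,potent hepatocarcinogen
Patulin,,C7H6O4,mycotoxin; genotoxic
Coniine,,C8H17N,hemlock alkaloid; neurotoxic
Anabasine,,C10H14N2,teratogenic alkaloid
Cytisine,,C11H14N2O,nicotinic alkaloid; toxic
Aconitine,,C34H47NO11,cardiotoxic and neurotoxic alkaloid
Pyrogallol,"1,2,3-trihydroxybenzene",C6H6O3,toxic phenol; methaemoglobinaemia
Phlorizin,phloridzin,C21H24O10,dihydrochalcone glycoside; renal glycosuria
Oxalic acid,ethanedioic acid,C2H2O4,corrosive; nephrotoxic via oxalate
Scopolamine,hyoscine,C17H21NO4,anticholinergic alkaloid; deliriant
Sparteine,,C15H26N2,quinolizidine alkaloid; cardiotoxic
Senecionine,,C18H25NO5,pyrrolizidine alkaloid; hepatotoxic and genotoxic
Retrorsine,,C18H25NO6,pyrrolizidine alkaloid; hepatotoxic
Cucurbitacin E,,C32H44O8,bitter triterpenoid; acutely toxic
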