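name,rt,not_in_blank,above_noise,good_peak_shape,isotopic_match,chemspider_matches,extractables_matches,msms
Citric acid,2.46,TRUE,TRUE,FALSE,[M-H],12,2,89.4%
Gallic acid,3.72,TRUE,TRUE,TRUE,[M-H],16,0,no match
L-Aspartic acid,1.73,TRUE,TRUE,TRUE,[M-H],21,0,96.8
L-Glutamic acid,1.73,TRUE,TRUE,TRUE,[M-H],50,0,99.50%
Naringin,22.93,TRUE,TRUE,TRUE,[M-H],12,0,80.30%
Salicylic acid,21.71,FALSE,TRUE,TRUE,[M-H],40,1,no MS/MS
Succinic acid,2.77,TRUE,TRUE,TRUE,[M-H],16,1,no MS/MS
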