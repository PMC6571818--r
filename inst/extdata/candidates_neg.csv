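name,formula,rt,polarity
Citric acid,C6H8O7,2.46,neg
Gallic acid,C7H6O5,3.72,neg
L-Aspartic acid,C4H7NO4,1.73,neg
L-Glutamic acid,C5H9NO4,1.73,neg
Naringin,C27H32O14,22.93,neg
Salicylic acid,C7H6O3,21.71,neg
Succinic acid,C4H6O4,2.77,neg
Malic acid,C4H6O5,1.95,neg
Quinic acid,C7H12O6,1.50,neg
Tartaric acid,C4H6O6,1.60,neg
Fumaric acid,C4H4O4,2.20,neg
Shikimic acid,C7H10O5,1.80,neg
Chlorogenic acid,C16H18O9,8.70,neg
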