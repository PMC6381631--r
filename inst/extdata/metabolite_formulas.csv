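compound,formula,panel
ADP,C10H15N5O10P2,15N
ATP,C10H16N5O13P3,15N
CTP,C9H16N3O14P3,15N
GDP,C10H15N5O11P2,15N
N-acetyl-glutamate,C7H11NO5,15N
N-acetyl-glutamine,C7H12N2O4,15N
N-carbamoyl-L-aspartate,C5H8N2O5,15N
UDP,C9H14N2O12P2,15N
UDP-D-glucose,C15H24N2O17P2,15N
UDP-N-acetyl-glucosamine,C17H27N3O17P2,15N
UTP,C9H15N2O15P3,15N
arginine,C6H14N4O2,15N
asparagine,C4H8N2O3,15N
citrulline,C6H13N3O3,15N
glutamate,C5H9NO4,15N
glutamine,C5H10N2O3,15N
glutathione,C10H17N3O6S,15N
glutathione disulfide,C20H32N6O12S2,15N
lysine,C6H14N2O2,15N
ornithine,C5H12N2O2,15N
phenylalanine,C9H11NO2,15N
serine,C3H7NO3,15N
tryptophan,C11H12N2O2,15N
uridine,C9H12N2O6,15N
thiamine pyrophosphate,C12H18N4O7P2S,34S
glutathione disulfide,C20H32N6O12S2,34S
S-adenosyl-methionine,C15H22N6O5S,34S
cystathionine,C7H14N2O4S,34S
cystine,C6H12N2O4S2,34S
glutathione,C10H17N3O6S,34S
cysteine,C3H7NO2S,34S
thiamine,C12H16N4OS,34S
taurine,C2H7NO3S,34S
methionine,C5H11NO2S,34S
coenzyme A,C21H36N7O16P3S,CoA
acetyl-CoA,C23H38N7O17P3S,CoA
succinyl-CoA,C25H40N7O19P3S,CoA
HMG-CoA,C27H44N7O20P3S,CoA
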