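# Hand-verified fixture molecules. expected_mw is the sum of standard
# atomic weights (H 1.008, C 12.011, N 14.007, O 15.999) over all atoms,
# hydrogens included, computed by hand from the molecular formula.
name,smiles,formula,expected_mw
neon,[Ne],Ne,20.180
hydrogen,[H][H],H2,2.016
methane,C,CH4,16.043
ethane,CC,C2H6,30.070
ethene,C=C,C2H4,28.054
ethyne,C#C,C2H2,26.038
ethanol,CCO,C2H6O,46.069
benzene,c1ccccc1,C6H6,78.114
pyridine,c1ccncc1,C5H5N,79.102
aspirin,CC(=O)Oc1ccccc1C(=O)O,C9H8O4,180.159
caffeine,CN1C=NC2=C1C(=O)N(C(=O)N2C)C,C8H10N4O2,194.194
paracetamol,CC(=O)Nc1ccc(O)cc1,C8H9NO2,151.165
ibuprofen,CC(C)Cc1ccc(cc1)C(C)C(=O)O,C13H18O2,206.285
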