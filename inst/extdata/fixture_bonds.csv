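# Hand-enumerated bond multisets of the fixture molecules after explicit-H
# addition and kekulization. Each molecule was enumerated twice
# independently (double entry) and the totals checked against
# n_bonds = n_atoms - 1 + n_rings. Derivation notes:
#   neon        monoatomic, no bonds.
#   hydrogen    H-H.
#   methane     4 C-H.
#   ethane      C-C + 6 C-H.
#   ethene      C=C + 4 C-H.
#   ethyne      C#C + 2 C-H.
#   ethanol     C-C, C-O, O-H, 5 C-H (8 bonds; 9 atoms, 0 rings).
#   benzene     kekulized ring 3 C-C + 3 C=C, 6 C-H (12 bonds).
#   pyridine    ring N=C,C-C,C=C,C-C,C=C,C-N (either Kekule structure gives
#               1 C=N, 1 C-N, 2 C=C, 2 C-C), 5 C-H (11 bonds).
#   aspirin     CH3: 3 C-H; CH3-C(=O): C-C; acetyl C=O; ester C-O x2
#               (acyl-O and O-ring); ring 3 C-C + 3 C=C + 4 C-H;
#               ring-COOH C-C; carboxyl C=O, C-O, O-H.
#               Totals: 7 C-H, 1 O-H, 5 C-C, 3 C=C, 2 C=O, 3 C-O = 21 bonds
#               (21 atoms, 1 ring); 8 hydrogens as in C9H8O4.
#   caffeine    SMILES CN1C=NC2=C1C(=O)N(C(=O)N2C)C fixes the Kekule form:
#               N-CH3 x3, ring N-C singles (b-c,d-e,f-b,g-i? see below),
#               enumerated atom-by-atom: C-N singles a-b,b-c? no:
#               methyl-N x3 (a-b, l-m, i-n), ring singles b-c, d-e, f-b,
#               g-i, i-j, j-l, l-e = 10 C-N total; c=d C=N; f-g C-C;
#               e=f C=C; g=h, j=k C=O; 10 C-H (3+1+3+3).
#               Totals: 10 C-N, 1 C=N, 1 C-C, 1 C=C, 2 C=O, 10 C-H =
#               25 bonds (24 atoms, 2 rings).
#   paracetamol CH3: 3 C-H; CH3-C(=O): C-C; amide C=O, C-N; N-H; N-ring C-N;
#               ring 3 C-C + 3 C=C + 4 C-H; ring-O C-O; O-H.
#               Totals: 7 C-H, 1 N-H, 1 O-H, 4 C-C, 3 C=C, 1 C=O, 2 C-N,
#               1 C-O = 20 bonds (20 atoms, 1 ring).
#   ibuprofen   isobutyl 2x CH3-CH + CH-CH2 + CH2-ring = 4 C-C; propanoate
#               side ring-CH + CH-CH3 + CH-COOH = 3 C-C; ring 3 C-C singles;
#               total 10 C-C; ring 3 C=C; carboxyl C=O, C-O, O-H;
#               17 C-H (18 H minus the O-H). 33 bonds (33 atoms, 1 ring).
name,element_a,element_b,order,count
hydrogen,H,H,1,1
methane,C,H,1,4
ethane,C,C,1,1
ethane,C,H,1,6
ethene,C,C,2,1
ethene,C,H,1,4
ethyne,C,C,3,1
ethyne,C,H,1,2
ethanol,C,C,1,1
ethanol,C,O,1,1
ethanol,O,H,1,1
ethanol,C,H,1,5
benzene,C,C,1,3
benzene,C,C,2,3
benzene,C,H,1,6
pyridine,C,N,1,1
pyridine,C,N,2,1
pyridine,C,C,1,2
pyridine,C,C,2,2
pyridine,C,H,1,5
aspirin,C,H,1,7
aspirin,O,H,1,1
aspirin,C,C,1,5
aspirin,C,C,2,3
aspirin,C,O,2,2
aspirin,C,O,1,3
caffeine,C,H,1,10
caffeine,C,N,1,10
caffeine,C,N,2,1
caffeine,C,C,1,1
caffeine,C,C,2,1
caffeine,C,O,2,2
paracetamol,C,H,1,7
paracetamol,N,H,1,1
paracetamol,O,H,1,1
paracetamol,C,C,1,4
paracetamol,C,C,2,3
paracetamol,C,O,2,1
paracetamol,C,N,1,2
paracetamol,C,O,1,1
ibuprofen,C,H,1,17
ibuprofen,O,H,1,1
ibuprofen,C,C,1,10
ibuprofen,C,C,2,3
ibuprofen,C,O,2,1
ibuprofen,C,O,1,1
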