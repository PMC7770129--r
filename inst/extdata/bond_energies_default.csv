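# Average bond enthalpies (kJ/mol), gas phase, 298 K.
# Transcribed from the standard general-chemistry reference tables of
# average bond energies; each value checked against the reference by hand.
# Columns: element_a, element_b, order (1 single / 2 double / 3 triple),
# energy_kj_mol. Keys are symmetric in the two elements.
element_a,element_b,order,energy_kj_mol
H,H,1,436
C,H,1,413
N,H,1,391
O,H,1,467
S,H,1,347
P,H,1,322
Si,H,1,318
F,H,1,567
Cl,H,1,431
Br,H,1,366
I,H,1,299
C,C,1,347
C,C,2,614
C,C,3,839
C,N,1,305
C,N,2,615
C,N,3,891
C,O,1,358
C,O,2,745
C,O,3,1072
C,S,1,259
C,S,2,573
C,F,1,485
C,Cl,1,339
C,Br,1,276
C,I,1,240
C,Si,1,301
C,P,1,264
N,N,1,163
N,N,2,418
N,N,3,941
N,O,1,201
N,O,2,607
N,F,1,272
N,Cl,1,200
N,Br,1,243
O,O,1,146
O,O,2,495
O,F,1,190
O,Cl,1,203
O,I,1,234
O,Si,1,452
O,P,1,335
O,P,2,544
O,S,2,523
S,S,1,266
S,S,2,418
S,F,1,327
S,Cl,1,253
S,Br,1,218
F,F,1,155
Cl,Cl,1,242
Br,Br,1,193
I,I,1,151
Cl,I,1,208
Br,I,1,175
Br,Cl,1,218
P,P,1,201
Si,Si,1,226
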