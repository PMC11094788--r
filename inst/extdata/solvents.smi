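# Common laboratory solvents, one SMILES per line.
# Entries are canonicalized on load; membership tests use canonical forms.
O
CCO
CO
CC(C)O
CCCCO
CC(C)(C)O
CC#N
ClCCl
ClC(Cl)Cl
ClC(Cl)(Cl)Cl
C1CCOC1
C1COCCO1
COCCOC
CCOCC
COC(C)(C)C
Cc1ccccc1
c1ccccc1
Cc1ccccc1C
CN(C)C=O
CN(C)C(C)=O
CS(C)=O
CC(=O)O
CCOC(C)=O
COC(C)=O
CC(C)=O
CCC(C)=O
CC(C)CC(C)=O
O=C1CCCCC1
CCCCCC
CCCCCCC
C1CCCCC1
CC1CCCCC1
CCCCC
CCCCCCCC
N#Cc1ccccc1
Clc1ccccc1
Clc1ccccc1Cl
CC(C)CO
CCC(C)O
CCCO
CCCCCO
OCCO
OCCCO
COCCO
CCOCCO
C1CCNC1
CN1CCCC1=O
O=CN(C)C
CCCC#N
OCC(F)(F)F
FC(F)(F)c1ccccc1
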