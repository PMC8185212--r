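residue,atom,element,hydrogens,aromatic
ALA,N,N,1,0
ALA,CA,C,1,0
ALA,C,C,0,0
ALA,O,O,0,0
ALA,CB,C,3,0
ARG,N,N,1,0
ARG,CA,C,1,0
ARG,C,C,0,0
ARG,O,O,0,0
ARG,CB,C,2,0
ARG,CG,C,2,0
ARG,CD,C,2,0
ARG,NE,N,1,0
ARG,CZ,C,0,0
ARG,NH1,N,2,0
ARG,NH2,N,2,0
ASN,N,N,1,0
ASN,CA,C,1,0
ASN,C,C,0,0
ASN,O,O,0,0
ASN,CB,C,2,0
ASN,CG,C,0,0
ASN,OD1,O,0,0
ASN,ND2,N,2,0
ASP,N,N,1,0
ASP,CA,C,1,0
ASP,C,C,0,0
ASP,O,O,0,0
ASP,CB,C,2,0
ASP,CG,C,0,0
ASP,OD1,O,0,0
ASP,OD2,O,0,0
CYS,N,N,1,0
CYS,CA,C,1,0
CYS,C,C,0,0
CYS,O,O,0,0
CYS,CB,C,2,0
CYS,SG,S,1,0
GLN,N,N,1,0
GLN,CA,C,1,0
GLN,C,C,0,0
GLN,O,O,0,0
GLN,CB,C,2,0
GLN,CG,C,2,0
GLN,CD,C,0,0
GLN,OE1,O,0,0
GLN,NE2,N,2,0
GLU,N,N,1,0
GLU,CA,C,1,0
GLU,C,C,0,0
GLU,O,O,0,0
GLU,CB,C,2,0
GLU,CG,C,2,0
GLU,CD,C,0,0
GLU,OE1,O,0,0
GLU,OE2,O,0,0
GLY,N,N,1,0
GLY,CA,C,2,0
GLY,C,C,0,0
GLY,O,O,0,0
HIS,N,N,1,0
HIS,CA,C,1,0
HIS,C,C,0,0
HIS,O,O,0,0
HIS,CB,C,2,0
HIS,CG,C,0,1
HIS,ND1,N,1,1
HIS,CD2,C,1,1
HIS,CE1,C,1,1
HIS,NE2,N,0,1
ILE,N,N,1,0
ILE,CA,C,1,0
ILE,C,C,0,0
ILE,O,O,0,0
ILE,CB,C,1,0
ILE,CG1,C,2,0
ILE,CG2,C,3,0
ILE,CD1,C,3,0
LEU,N,N,1,0
LEU,CA,C,1,0
LEU,C,C,0,0
LEU,O,O,0,0
LEU,CB,C,2,0
LEU,CG,C,1,0
LEU,CD1,C,3,0
LEU,CD2,C,3,0
LYS,N,N,1,0
LYS,CA,C,1,0
LYS,C,C,0,0
LYS,O,O,0,0
LYS,CB,C,2,0
LYS,CG,C,2,0
LYS,CD,C,2,0
LYS,CE,C,2,0
LYS,NZ,N,3,0
MET,N,N,1,0
MET,CA,C,1,0
MET,C,C,0,0
MET,O,O,0,0
MET,CB,C,2,0
MET,CG,C,2,0
MET,SD,S,0,0
MET,CE,C,3,0
PHE,N,N,1,0
PHE,CA,C,1,0
PHE,C,C,0,0
PHE,O,O,0,0
PHE,CB,C,2,0
PHE,CG,C,0,1
PHE,CD1,C,1,1
PHE,CD2,C,1,1
PHE,CE1,C,1,1
PHE,CE2,C,1,1
PHE,CZ,C,1,1
PRO,N,N,0,0
PRO,CA,C,1,0
PRO,C,C,0,0
PRO,O,O,0,0
PRO,CB,C,2,0
PRO,CG,C,2,0
PRO,CD,C,2,0
SER,N,N,1,0
SER,CA,C,1,0
SER,C,C,0,0
SER,O,O,0,0
SER,CB,C,2,0
SER,OG,O,1,0
THR,N,N,1,0
THR,CA,C,1,0
THR,C,C,0,0
THR,O,O,0,0
THR,CB,C,1,0
THR,OG1,O,1,0
THR,CG2,C,3,0
TRP,N,N,1,0
TRP,CA,C,1,0
TRP,C,C,0,0
TRP,O,O,0,0
TRP,CB,C,2,0
TRP,CG,C,0,1
TRP,CD1,C,1,1
TRP,CD2,C,0,1
TRP,NE1,N,1,1
TRP,CE2,C,0,1
TRP,CE3,C,1,1
TRP,CZ2,C,1,1
TRP,CZ3,C,1,1
TRP,CH2,C,1,1
TYR,N,N,1,0
TYR,CA,C,1,0
TYR,C,C,0,0
TYR,O,O,0,0
TYR,CB,C,2,0
TYR,CG,C,0,1
TYR,CD1,C,1,1
TYR,CD2,C,1,1
TYR,CE1,C,1,1
TYR,CE2,C,1,1
TYR,CZ,C,0,1
TYR,OH,O,1,0
VAL,N,N,1,0
VAL,CA,C,1,0
VAL,C,C,0,0
VAL,O,O,0,0
VAL,CB,C,1,0
VAL,CG1,C,3,0
VAL,CG2,C,3,0
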