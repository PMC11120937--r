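residue,atom,donor,acceptor,aromatic
*,N,1,0,0
*,O,0,1,0
*,OXT,0,1,0
PRO,N,0,0,0
ARG,NE,1,0,0
ARG,NH1,1,0,0
ARG,NH2,1,0,0
LYS,NZ,1,0,0
HIS,ND1,1,1,0
HIS,NE2,1,1,0
HIS,CG,0,0,1
HIS,CD2,0,0,1
HIS,CE1,0,0,1
TRP,NE1,1,0,1
TRP,CG,0,0,1
TRP,CD1,0,0,1
TRP,CD2,0,0,1
TRP,CE2,0,0,1
TRP,CE3,0,0,1
TRP,CZ2,0,0,1
TRP,CZ3,0,0,1
TRP,CH2,0,0,1
PHE,CG,0,0,1
PHE,CD1,0,0,1
PHE,CD2,0,0,1
PHE,CE1,0,0,1
PHE,CE2,0,0,1
PHE,CZ,0,0,1
TYR,CG,0,0,1
TYR,CD1,0,0,1
TYR,CD2,0,0,1
TYR,CE1,0,0,1
TYR,CE2,0,0,1
TYR,CZ,0,0,1
TYR,OH,1,1,0
SER,OG,1,1,0
THR,OG1,1,1,0
CYS,SG,1,1,0
MET,SD,0,1,0
ASN,ND2,1,0,0
ASN,OD1,0,1,0
GLN,NE2,1,0,0
GLN,OE1,0,1,0
ASP,OD1,0,1,0
ASP,OD2,0,1,0
GLU,OE1,0,1,0
GLU,OE2,0,1,0
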