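residue_name,atom_name,shift_ppm
ALA,CA,52.5
ALA,CB,19.1
ALA,N,123.8
ALA,H,8.24
ALA,HA,4.32
ARG,CA,56.0
ARG,CB,30.9
ARG,N,120.5
ARG,H,8.23
ARG,HA,4.34
ASN,CA,53.1
ASN,CB,38.9
ASN,N,118.7
ASN,H,8.40
ASN,HA,4.74
ASP,CA,54.2
ASP,CB,41.1
ASP,N,120.4
ASP,H,8.34
ASP,HA,4.64
CYS,CA,58.2
CYS,CB,28.0
CYS,N,118.8
CYS,H,8.32
CYS,HA,4.55
GLN,CA,55.7
GLN,CB,29.4
GLN,N,119.8
GLN,H,8.32
GLN,HA,4.34
GLU,CA,56.6
GLU,CB,29.9
GLU,N,120.2
GLU,H,8.42
GLU,HA,4.35
GLY,CA,45.1
GLY,N,108.8
GLY,H,8.33
GLY,HA,3.96
HIS,CA,55.0
HIS,CB,29.0
HIS,N,118.2
HIS,H,8.42
HIS,HA,4.73
ILE,CA,61.1
ILE,CB,38.8
ILE,N,119.9
ILE,H,8.00
ILE,HA,4.17
LEU,CA,55.1
LEU,CB,42.4
LEU,N,121.8
LEU,H,8.16
LEU,HA,4.38
LYS,CA,56.2
LYS,CB,33.1
LYS,N,120.4
LYS,H,8.29
LYS,HA,4.36
MET,CA,55.4
MET,CB,32.9
MET,N,119.6
MET,H,8.28
MET,HA,4.48
PHE,CA,57.7
PHE,CB,39.6
PHE,N,120.3
PHE,H,8.30
PHE,HA,4.62
PRO,CA,63.3
PRO,CB,32.1
PRO,CG,27.2
PRO,N,128.1
PRO,HA,4.42
SER,CA,58.3
SER,CB,63.8
SER,N,115.7
SER,H,8.31
SER,HA,4.47
THR,CA,61.8
THR,CB,69.8
THR,N,113.6
THR,H,8.15
THR,HA,4.35
TRP,CA,57.5
TRP,CB,29.6
TRP,N,121.3
TRP,H,8.25
TRP,HA,4.66
TYR,CA,57.9
TYR,CB,38.8
TYR,N,120.3
TYR,H,8.28
TYR,HA,4.55
VAL,CA,62.2
VAL,CB,32.9
VAL,N,119.2
VAL,H,8.03
VAL,HA,4.12
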