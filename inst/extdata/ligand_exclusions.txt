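# Chemical component codes excluded from ligand-binding analysis:
# water and unknowns, common crystallographic additives / cryoprotectants /
# buffer components, and modified amino-acid residues. One code per line;
# lines starting with '#' are ignored. Users may extend or replace this list.
HOH
DOD
UNL
UNX
UNK
# additives, cryoprotectants, buffers, precipitants
GOL
EDO
PEG
PG4
PGE
P6G
MPD
IPA
EOH
MOH
DMS
BME
MES
EPE
TRS
FMT
ACT
ACY
CIT
FLC
TLA
SO4
PO4
NO3
NH4
AZI
SCN
BCT
CO3
NA
CL
K
BR
IOD
CS
RB
LI
F
# modified / nonstandard amino-acid residues
MSE
CME
CSO
CSD
OCS
SEP
TPO
PTR
MLY
M3L
HYP
KCX
LLP
PCA
SAC
ALY
CSX
SMC
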