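comp_name	category
ALA	protein
ARG	protein
ASN	protein
ASP	protein
CYS	protein
GLN	protein
GLU	protein
GLY	protein
HIS	protein
ILE	protein
LEU	protein
LYS	protein
MET	protein
MSE	protein
PHE	protein
PRO	protein
SER	protein
THR	protein
TRP	protein
TYR	protein
VAL	protein
HOH	water
WAT	water
DOD	water
MAN	saccharide
BMA	saccharide
GLC	saccharide
BGC	saccharide
GAL	saccharide
GLA	saccharide
GCS	saccharide
PA1	saccharide
NAG	saccharide
NDG	saccharide
FUC	saccharide
XYS	saccharide
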