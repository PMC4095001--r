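# Residue polarity dialect (COCOMAPS-style).
# hydrophobic: ALA VAL LEU ILE MET PHE PRO TRP GLY
# hydrophilic: the remaining 11 standard residues (incl. CYS, TYR, HIS)
resname	class
ALA	hydrophobic
VAL	hydrophobic
LEU	hydrophobic
ILE	hydrophobic
MET	hydrophobic
PHE	hydrophobic
PRO	hydrophobic
TRP	hydrophobic
GLY	hydrophobic
ARG	hydrophilic
ASN	hydrophilic
ASP	hydrophilic
CYS	hydrophilic
GLN	hydrophilic
GLU	hydrophilic
HIS	hydrophilic
LYS	hydrophilic
SER	hydrophilic
THR	hydrophilic
TYR	hydrophilic
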