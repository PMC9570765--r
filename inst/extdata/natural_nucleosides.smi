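# Natural nucleoside monomers (neutral, no phosphate); T is 2'-deoxythymidine
A	OCC1OC(n2cnc3c(N)ncnc32)C(O)C1O
C	NC1=NC(=O)N(C=C1)C1OC(CO)C(O)C1O
G	NC1=NC2=C(N=CN2C2OC(CO)C(O)C2O)C(=O)N1
U	O=C1C=CN(C2OC(CO)C(O)C2O)C(=O)N1
T	CC1=CN(C2CC(O)C(CO)O2)C(=O)NC1=O
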