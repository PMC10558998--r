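label,region
Fp1,AF
Fp2,AF
AF7,AF
AF3,AF
AF4,AF
AF8,AF
F7,LFC
F5,LFC
F3,LFC
FT7,LFC
FC5,LFC
FC3,LFC
F1,MFC
Fz,MFC
F2,MFC
FC1,MFC
FC2,MFC
F4,RFC
F6,RFC
F8,RFC
FC4,RFC
FC6,RFC
FT8,RFC
C5,LCP
C3,LCP
C1,LCP
CP5,LCP
CP3,LCP
CP1,LCP
Cz,MCP
CPz,MCP
C2,RCP
C4,RCP
C6,RCP
CP2,RCP
CP4,RCP
CP6,RCP
P7,LPO
P5,LPO
P3,LPO
P1,LPO
PO7,LPO
PO3,LPO
Pz,MPO
POz,MPO
P2,RPO
P4,RPO
P6,RPO
P8,RPO
PO4,RPO
PO8,RPO
FT9,LT
T7,LT
TP7,LT
FT10,RT
T8,RT
TP8,RT
O1,O
Oz,O
O2,O
TP9,LT
TP10,RT
PO9,LPO
PO10,RPO
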