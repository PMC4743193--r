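label,x,y
FP1,-0.25,0.95
FP2,0.25,0.95
AF7,-0.55,0.8
AF3,-0.25,0.8
AF4,0.25,0.8
AF8,0.55,0.8
F7,-0.8,0.6
F5,-0.6,0.6
F3,-0.4,0.6
F1,-0.2,0.6
Fz,0,0.6
F2,0.2,0.6
F4,0.4,0.6
F6,0.6,0.6
F8,0.8,0.6
FT7,-0.8,0.3
FC5,-0.6,0.3
FC3,-0.4,0.3
FC1,-0.2,0.3
FCz,0,0.3
FC2,0.2,0.3
FC4,0.4,0.3
FC6,0.6,0.3
FT8,0.8,0.3
T7,-0.8,0
C5,-0.6,0
C3,-0.4,0
C1,-0.2,0
Cz,0,0
C2,0.2,0
C4,0.4,0
C6,0.6,0
T8,0.8,0
TP7,-0.8,-0.3
CP5,-0.6,-0.3
CP3,-0.4,-0.3
CP1,-0.2,-0.3
CPz,0,-0.3
CP2,0.2,-0.3
CP4,0.4,-0.3
CP6,0.6,-0.3
TP8,0.8,-0.3
P7,-0.8,-0.6
P5,-0.6,-0.6
P3,-0.4,-0.6
P1,-0.2,-0.6
Pz,0,-0.6
P2,0.2,-0.6
P4,0.4,-0.6
P6,0.6,-0.6
P8,0.8,-0.6
PO7,-0.55,-0.8
POz,0,-0.8
PO8,0.55,-0.8
O1,-0.25,-0.95
O2,0.25,-0.95
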