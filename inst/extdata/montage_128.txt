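Fp1
Fp2
F7
F3
Fz
F4
F8
FC5
FC1
FC2
FC6
T7
C3
Cz
C4
T8
TP9
CP5
CP1
CP2
CP6
TP10
P7
P3
Pz
P4
P8
PO9
O1
Oz
O2
PO10
AF7
AF3
AF4
AF8
F5
F1
F2
F6
FT9
FT7
FC3
FC4
FT8
FT10
C5
C1
C2
C6
TP7
CP3
CPz
CP4
TP8
P5
P1
P2
P6
PO7
PO3
POz
PO4
PO8
Fpz
AFz
FCz
Iz
F9
F10
P9
P10
AFp1
AFp2
AFF1h
AFF2h
AFF5h
AFF6h
FFC1h
FFC2h
FFC3h
FFC4h
FFC5h
FFC6h
FFT7h
FFT8h
FFT9h
FFT10h
FCC1h
FCC2h
FCC3h
FCC4h
FCC5h
FCC6h
FTT7h
FTT8h
FTT9h
FTT10h
CCP1h
CCP2h
CCP3h
CCP4h
CCP5h
CCP6h
TTP7h
TTP8h
CPP1h
CPP2h
CPP3h
CPP4h
CPP5h
CPP6h
TPP7h
TPP8h
TPP9h
TPP10h
PPO1h
PPO2h
PPO5h
PPO6h
PPO9h
PPO10h
POO1
POO2
POO9h
POO10h
OI1h
OI2h
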