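PE O-16:1_18:1
PE O-18:1_18:1
PE O-18:2_18:1
PC 16:0_18:1
PC 18:0_18:1
PC O-16:1_20:4
CE 20:4
CE 18:2
CE 22:6
PS 18:1_18:1
PS 18:0_18:1
PA 18:0_18:1
PA 18:1_18:1
PA 18:1_22:0
PA 18:0_20:4
PG 16:0_18:1
PI 18:0_20:4
PI O-16:0_18:1
DG 16:0_18:1
CL 16:0_18:1_18:1_18:2
LPC 18:1
LPE 18:0
LPI 20:4
SM 18:1;O2/16:0
Cer 18:1;O2/24:1
HexCer 18:1;O2/24:1
SHexCer 18:1;O2/24:1
PSY 18:1;O2
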