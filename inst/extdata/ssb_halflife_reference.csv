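protein,temperature_c,half_life_min
DpsSSB,100,5
DpsSSB,95,5
DpsSSB,90,15
DpsSSB,85,30
DpsSSB,80,30
DpsSSB,60,60
FpsSSB,100,5
FpsSSB,95,5
FpsSSB,90,15
FpsSSB,85,30
FpsSSB,80,45
FpsSSB,75,60
ParSSB,100,15
ParSSB,95,30
ParSSB,90,45
ParSSB,85,60
PcrSSB,100,30
PcrSSB,95,45
PcrSSB,90,60
PinSSB,100,15
PinSSB,95,15
PinSSB,90,15
PinSSB,85,30
PinSSB,80,60
PprSSB,100,15
PprSSB,95,30
PprSSB,90,45
PprSSB,85,60
PtoSSB,100,5
PtoSSB,95,5
PtoSSB,90,10
PtoSSB,85,15
PtoSSB,80,15
PtoSSB,70,30
PtoSSB,65,45
PtoSSB,60,60
EcoSSB,100,15
EcoSSB,95,30
EcoSSB,90,45
EcoSSB,85,60
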