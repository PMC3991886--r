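protein,duplex_tm_free_c,duplex_tm_complex_c,dsc_tm_c
DpsSSB,75,70,78.5
FpsSSB,75,69,69.4
ParSSB,75,67,59.9
PcrSSB,75,64,63.0
PinSSB,75,69,57.9
PtoSSB,75,58,58.7
PprSSB,75,65,59.5
EcoSSB,75,62,69.0
TmaSSB,NA,NA,109.3
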