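protein,monomer_mass_kda,length_aa,cterm_length_aa,last_residues,pi,aliphatic_index,cys_count,native_mass_kda
DpsSSB,15.6,142,37,DVPF,5.46,61.20,1,59
FpsSSB,15.9,140,31,DLPF,5.94,73.07,2,69.5
ParSSB,22.8,213,105,DIPF,5.91,49.11,0,94.4
PcrSSB,23.3,219,111,DIPF,5.70,43.29,0,96.1
PinSSB,25.1,222,112,DIPF,7.79,41.80,1,102.8
PtoSSB,17.1,151,43,DLPF,5.67,61.32,3,72.3
PprSSB,20.4,183,76,DIPF,5.43,54.37,0,85.4
EcoSSB,18.9,178,73,DIPF,5.44,56.97,0,NA
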