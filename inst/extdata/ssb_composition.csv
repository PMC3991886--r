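protein,length,A,I,L,V,M,G,P,K,R,D,E,Q,N,S,T,H,W,F,Y,C
DpsSSB,142,7.0,6.3,4.9,3.5,2.8,11.3,4.2,4.2,7.0,4.9,7.7,4.9,6.3,9.2,7.0,0.7,2.8,1.4,2.8,0.7
FpsSSB,140,4.3,7.9,5.0,6.4,2.1,6.4,2.1,10.0,2.9,5.0,9.3,2.1,7.1,8.0,10.7,2.1,1.4,4.3,3.6,1.4
ParSSB,213,8.0,5.2,3.3,2.8,1.9,16.4,4.7,4.2,4.7,5.6,4.2,12.2,8.0,5.6,4.2,1.4,0.9,3.3,3.3,0
PcrSSB,219,6.8,4.6,2.7,2.7,1.8,16.9,4.6,3.7,4.6,5.0,4.1,12.8,10.0,7.3,4.1,0.9,0.9,3.2,3.2,0
PinSSB,222,7.7,1.8,3.6,4.5,3.6,6.8,9.9,5.9,4.5,4.5,5.4,17.6,6.3,3.6,6.3,0.9,1.8,2.3,2.7,0.5
PprSSB,183,7.7,3.3,3.8,6.6,2.7,10.4,7.1,3.8,4.4,3.8,5.5,21.3,4.4,3.8,3.8,0.5,2.2,2.2,2.7,0
PtoSSB,151,5.3,5.3,4.6,6.0,2.6,6.0,7.3,10.6,2.6,5.3,9.9,5.3,4.6,3.3,9.3,2.0,1.3,3.3,3.3,2.0
EcoSSB,178,7.3,2.8,4.5,7.3,3.4,16.3,6.7,3.4,5.6,4.5,5.6,10.1,4.5,5.6,5.0,0.6,2.2,2.2,2.2,0
TteSSB3,NA,4.0,5.3,7.3,8.7,2.0,6.0,6.0,5.3,6.0,10.7,8.0,1.3,4.0,6.7,8.0,0.7,2.0,6.0,1.3,0
TmaSSB,NA,5.0,4.3,5.7,9.2,2.8,4.3,7.1,3.5,10.6,6.4,12.8,0.7,2.1,5.0,10.6,0,0.7,7.8,1.4,0
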