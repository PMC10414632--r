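class,CO,KOT,VK,RB,RH,SH
CO,27,9,1,3,1,5
KOT,3,39,10,0,9,1
VK,0,8,27,0,4,6
RB,5,3,0,40,3,2
RH,2,15,1,0,41,0
SH,5,4,0,3,2,40
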