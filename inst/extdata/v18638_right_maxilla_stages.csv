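specimen_id,taxon,element,side,position,kind,stage,label,skull_length_cm,provenance
IVPP V18638,Yinlong downsi,maxilla,right,1,functional,F3,M1,13.4,derived
IVPP V18638,Yinlong downsi,maxilla,right,1,replacement,R1,rM1,13.4,derived
IVPP V18638,Yinlong downsi,maxilla,right,2,functional,F2,M2,13.4,derived
IVPP V18638,Yinlong downsi,maxilla,right,2,replacement,R2,rM2,13.4,derived
IVPP V18638,Yinlong downsi,maxilla,right,3,functional,F1,M3,13.4,derived
IVPP V18638,Yinlong downsi,maxilla,right,4,empty_alveolus,NA,A4,13.4,text
IVPP V18638,Yinlong downsi,maxilla,right,5,functional,F3,M5,13.4,derived
IVPP V18638,Yinlong downsi,maxilla,right,6,functional,F2,M6,13.4,derived
IVPP V18638,Yinlong downsi,maxilla,right,7,empty_alveolus,NA,A7,13.4,text
IVPP V18638,Yinlong downsi,maxilla,right,8,functional,F2,M8,13.4,derived
IVPP V18638,Yinlong downsi,maxilla,right,9,functional,F1,M9,13.4,derived
IVPP V18638,Yinlong downsi,maxilla,right,10,functional,F4,M10,13.4,derived
IVPP V18638,Yinlong downsi,maxilla,right,10,replacement,R2,rM10,13.4,derived
IVPP V18638,Yinlong downsi,maxilla,right,11,functional,F3,M11,13.4,derived
IVPP V18638,Yinlong downsi,maxilla,right,12,empty_alveolus,NA,A12,13.4,text
IVPP V18638,Yinlong downsi,maxilla,right,13,functional,F3,M13,13.4,derived
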