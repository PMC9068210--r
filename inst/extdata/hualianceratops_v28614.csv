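specimen_id,taxon,element,side,position,kind,stage,label,skull_length_cm,note
IVPP V28614,Hualianceratops wucaiwanensis,dentary,left,1,functional,NA,D1,NA,replacement positions nominal; first functional tooth broken (root only)
IVPP V28614,Hualianceratops wucaiwanensis,dentary,left,2,functional,NA,D2,NA,replacement positions nominal; first functional tooth broken (root only)
IVPP V28614,Hualianceratops wucaiwanensis,dentary,left,2,replacement,NA,rD2,NA,replacement positions nominal; first functional tooth broken (root only)
IVPP V28614,Hualianceratops wucaiwanensis,dentary,left,3,functional,NA,D3,NA,replacement positions nominal; first functional tooth broken (root only)
IVPP V28614,Hualianceratops wucaiwanensis,dentary,left,4,functional,NA,D4,NA,replacement positions nominal; first functional tooth broken (root only)
IVPP V28614,Hualianceratops wucaiwanensis,dentary,left,4,replacement,NA,rD4,NA,replacement positions nominal; first functional tooth broken (root only)
IVPP V28614,Hualianceratops wucaiwanensis,dentary,left,5,functional,NA,D5,NA,replacement positions nominal; first functional tooth broken (root only)
IVPP V28614,Hualianceratops wucaiwanensis,dentary,left,6,functional,NA,D6,NA,replacement positions nominal; first functional tooth broken (root only)
IVPP V28614,Hualianceratops wucaiwanensis,dentary,left,6,replacement,NA,rD6,NA,replacement positions nominal; first functional tooth broken (root only)
IVPP V28614,Hualianceratops wucaiwanensis,dentary,left,7,functional,NA,D7,NA,replacement positions nominal; first functional tooth broken (root only)
IVPP V28614,Hualianceratops wucaiwanensis,dentary,left,8,functional,NA,D8,NA,replacement positions nominal; first functional tooth broken (root only)
IVPP V28614,Hualianceratops wucaiwanensis,dentary,left,8,replacement,NA,rD8,NA,replacement positions nominal; first functional tooth broken (root only)
IVPP V28614,Hualianceratops wucaiwanensis,dentary,left,9,functional,NA,D9,NA,replacement positions nominal; first functional tooth broken (root only)
IVPP V28614,Hualianceratops wucaiwanensis,dentary,left,10,functional,NA,D10,NA,replacement positions nominal; first functional tooth broken (root only)
IVPP V28614,Hualianceratops wucaiwanensis,dentary,left,10,replacement,NA,rD10,NA,replacement positions nominal; first functional tooth broken (root only)
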