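case,hand,laterality,location,rating
case1,left,contralesional,digit_I_distal_phalanx,2
case1,left,contralesional,digit_II_metacarpal,2
case1,left,contralesional,digit_III_distal_phalanx,2
case1,left,contralesional,digit_V_distal_phalanx,2
case1,left,contralesional,digit_V_metacarpal,2
case1,left,contralesional,thenar_eminence,2
case1,right,ipsilesional,digit_I_distal_phalanx,2
case1,right,ipsilesional,digit_II_metacarpal,2
case1,right,ipsilesional,digit_III_distal_phalanx,2
case1,right,ipsilesional,digit_V_distal_phalanx,2
case1,right,ipsilesional,digit_V_metacarpal,2
case1,right,ipsilesional,thenar_eminence,2
case2,left,contralesional,digit_I_distal_phalanx,1
case2,left,contralesional,digit_II_metacarpal,0
case2,left,contralesional,digit_III_distal_phalanx,0
case2,left,contralesional,digit_V_distal_phalanx,1
case2,left,contralesional,digit_V_metacarpal,1
case2,left,contralesional,thenar_eminence,0
case2,right,ipsilesional,digit_I_distal_phalanx,2
case2,right,ipsilesional,digit_II_metacarpal,2
case2,right,ipsilesional,digit_III_distal_phalanx,1
case2,right,ipsilesional,digit_V_distal_phalanx,2
case2,right,ipsilesional,digit_V_metacarpal,1
case2,right,ipsilesional,thenar_eminence,2
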