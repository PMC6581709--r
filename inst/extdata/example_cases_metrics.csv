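case,hand,laterality,site_id,offset_cm,spread_cm
case1,left,contralesional,1,1.8,0.5
case1,left,contralesional,2,0.2,0.6
case1,left,contralesional,3,0.7,0.8
case1,left,contralesional,4,4.1,2.5
case1,left,contralesional,5,2.3,1.1
case1,left,contralesional,6,0.3,1.1
case1,left,contralesional,7,0.7,0.4
case1,left,contralesional,8,1.8,1.2
case1,left,contralesional,9,3.1,0.6
case1,left,contralesional,10,1.7,2.7
case1,left,contralesional,11,0.7,0.4
case1,left,contralesional,12,0.9,0.7
case1,left,contralesional,13,2.8,0.8
case1,left,contralesional,14,0.2,0.7
case1,left,contralesional,15,3.6,2.1
case1,left,contralesional,16,0.8,0.9
case1,left,contralesional,17,3,0.6
case1,left,contralesional,18,1.2,0.4
case1,left,contralesional,19,0.4,0.4
case1,left,contralesional,20,0.4,0.3
case1,left,contralesional,21,1.4,1
case1,left,contralesional,22,1.7,0.4
case1,left,contralesional,23,3.6,1.3
case1,left,contralesional,24,2.5,1.1
case1,right,ipsilesional,1,0.8,0.5
case1,right,ipsilesional,2,1.2,0.4
case1,right,ipsilesional,3,0.7,0.7
case1,right,ipsilesional,4,2.5,1.6
case1,right,ipsilesional,5,0.4,0.6
case1,right,ipsilesional,6,0.2,2.2
case1,right,ipsilesional,7,2,2.2
case1,right,ipsilesional,8,1.2,1
case1,right,ipsilesional,9,2.6,2.3
case1,right,ipsilesional,10,8.2,2.8
case1,right,ipsilesional,11,1.6,1.5
case1,right,ipsilesional,12,1.6,1
case1,right,ipsilesional,13,2,0.6
case1,right,ipsilesional,14,0.3,0.9
case1,right,ipsilesional,15,0.2,0.6
case1,right,ipsilesional,16,0.7,1.1
case1,right,ipsilesional,17,1.6,0.6
case1,right,ipsilesional,18,1.5,0.3
case1,right,ipsilesional,19,0.6,0.9
case1,right,ipsilesional,20,0.3,0.5
case1,right,ipsilesional,21,0.6,0.4
case1,right,ipsilesional,22,2.4,1
case1,right,ipsilesional,23,3,1.1
case1,right,ipsilesional,24,1.3,0.5
case2,left,contralesional,1,6.5,2.5
case2,left,contralesional,2,4.2,2.5
case2,left,contralesional,3,3.5,3.4
case2,left,contralesional,4,4.1,2.5
case2,left,contralesional,5,9.8,2.2
case2,left,contralesional,6,7.8,1.7
case2,left,contralesional,7,5,2
case2,left,contralesional,8,4,2.3
case2,left,contralesional,9,7.8,1.5
case2,left,contralesional,10,5.7,2.7
case2,left,contralesional,11,5.4,3.1
case2,left,contralesional,12,4.7,1.5
case2,left,contralesional,13,8.4,2.1
case2,left,contralesional,14,7,1.1
case2,left,contralesional,15,2.3,1.6
case2,left,contralesional,16,3.8,2.5
case2,left,contralesional,17,5.3,1.2
case2,left,contralesional,18,6.9,2
case2,left,contralesional,19,4.8,2
case2,left,contralesional,20,2.7,1.7
case2,left,contralesional,21,3.1,2.5
case2,left,contralesional,22,2.3,2.5
case2,left,contralesional,23,2.2,2
case2,left,contralesional,24,2.4,2.6
case2,right,ipsilesional,1,0.4,0.8
case2,right,ipsilesional,2,0.3,0.9
case2,right,ipsilesional,3,1.2,0.9
case2,right,ipsilesional,4,0.9,1.6
case2,right,ipsilesional,5,0.2,0.5
case2,right,ipsilesional,6,2.1,2.3
case2,right,ipsilesional,7,0.3,1.5
case2,right,ipsilesional,8,2.3,1.3
case2,right,ipsilesional,9,0.2,1.6
case2,right,ipsilesional,10,1.3,2.2
case2,right,ipsilesional,11,2.6,2.8
case2,right,ipsilesional,12,1.5,1.5
case2,right,ipsilesional,13,1.7,1
case2,right,ipsilesional,14,2.6,3.5
case2,right,ipsilesional,15,1.1,2.1
case2,right,ipsilesional,16,2.7,1.1
case2,right,ipsilesional,17,2.6,1.8
case2,right,ipsilesional,18,0.4,2
case2,right,ipsilesional,19,1.2,1
case2,right,ipsilesional,20,1.1,0.8
case2,right,ipsilesional,21,2.4,1.5
case2,right,ipsilesional,22,3.4,1.4
case2,right,ipsilesional,23,0.3,0.7
case2,right,ipsilesional,24,1.7,2.6
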