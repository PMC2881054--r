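case_id,pump_type,afterload,P_b_in,P_b_out,P_d_in,P_d_out,Q_b_in,Q_b_out,Q_d_in,Q_d_out,UF,blood_type
1,roller_centrifugal,TRUE,108,100,166,172,83,100,45,28,-17,saline
2,roller_centrifugal,TRUE,71,63,158,162,49,76,54,26,-28,saline
3,roller_centrifugal,TRUE,58,50,112,116,46,65,38,18,-20,saline
4,roller_centrifugal,TRUE,40,33,88,89,28,49,33,14,-20,saline
5,roller_centrifugal,TRUE,136,127,167,173,100,118,45,26,-18,saline
6,roller_centrifugal,TRUE,162,152,171,177,121,132,38,27,-10,saline
7,roller_centrifugal,TRUE,188,180,177,183,142,144,31,28,-3,saline
15,roller_centrifugal,FALSE,62,57,17,9,82,71,42,53,11,saline
16,roller_centrifugal,FALSE,27,23,8,2,40,39,43,44,2,saline
17,roller_centrifugal,FALSE,17,14,-1,-9,28,26,31,33,2,saline
18,roller_centrifugal,FALSE,13,10,-4,-12,20,19,24,26,2,saline
21,roller_centrifugal,FALSE,62,55,22,20,82,72,50,59,10,saline
22,roller_centrifugal,FALSE,44,37,9,9,65,58,40,47,7,saline
23,roller_centrifugal,FALSE,32,27,3,2,52,45,34,40,6,saline
24,roller_centrifugal,FALSE,22,19,-6,-8,42,36,20,26,6,saline
25,roller_centrifugal,FALSE,11,8,-13,-14,23,19,9,13,4,saline
31,WAK,TRUE,39,33,-25,-32,77,51,42,65,24,saline
32,WAK,TRUE,24,21,-24,-31,50,34,38,56,17,saline
33,WAK,TRUE,19,16,-21,-29,37,25,33,44,12,saline
34,WAK,TRUE,6,5,-19,-25,10,4,30,35,5.5,saline
35,WAK,TRUE,22,18,-22,-30,43,29,36,50,14,saline
41,WAK,FALSE,31,30,13,10,37,39,40,38,-2,porcine
44,WAK,FALSE,33,34,10,5,46,48,60,58,-2,porcine
47,WAK,FALSE,43,43,12,7,57,56,56,57,1,porcine
50,WAK,FALSE,51,45,7,-1,81,81,112,112,0,porcine
53,roller_centrifugal,FALSE,34,32,24,20,44,46,51,49,-2,porcine
56,roller_centrifugal,FALSE,36,35,26,24,51,54,67,64,-3,porcine
59,roller_centrifugal,FALSE,39,36,27,25,60,62,79,77,-2,porcine
62,roller_centrifugal,FALSE,55,48,34,27,82,84,112,110,-2,porcine
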