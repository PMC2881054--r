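case_id,solute,C_b_in,C_b_out,C_d_in,C_d_out
21,urea,118,73,0,95
21,creatinine,4.5,3,0,3.1
22,urea,118,68,0,95
22,creatinine,4.5,2.7,0,3.1
23,urea,118,56,0,88
23,creatinine,4.5,2.3,0,2.9
24,urea,118,60,0,100
24,creatinine,4.5,2.4,0,3.5
25,urea,118,61,0,99
25,creatinine,4.5,2.4,0,3.6
31,urea,38,24,0,31
31,creatinine,6.8,4.9,0,5.1
32,urea,38,8,0,21
32,creatinine,6.8,2.1,0,3.5
35,urea,38,4,0,18
35,creatinine,6.8,0.7,0,3.2
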