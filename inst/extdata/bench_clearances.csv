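case_id,solute,K_exp,K_num
21,urea,37,40
22,urea,31,34
23,urea,30,30
24,urea,24,24
25,urea,13,12
31,urea,44,48
32,urea,43,37
35,urea,40,34
41,urea,25,29
44,urea,32,35
47,urea,39,40
50,urea,52,51
53,urea,28,32
56,urea,35,33
59,urea,40,41
62,urea,52,50
21,creatinine,24,26
22,creatinine,21,22
23,creatinine,20,20
24,creatinine,16,16
25,creatinine,9,8
31,creatinine,28,32
32,creatinine,28,25
35,creatinine,28,22
41,creatinine,16,18
44,creatinine,21,22
47,creatinine,24,25
50,creatinine,31,30
53,creatinine,19,21
56,creatinine,22,20
59,creatinine,25,24
62,creatinine,31,30
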