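label,group,n_case,n_control,cc_case,ct_case,tt_case,cc_control,ct_control,tt_control
Synthetic A,east_asian,500,600,60,230,210,55,250,295
Synthetic B,east_asian,350,400,40,160,150,35,165,200
Synthetic C,east_asian,800,900,95,370,335,85,380,435
Synthetic D,caucasian,600,700,55,255,290,50,270,380
Synthetic E,caucasian,450,500,40,190,220,35,195,270
Synthetic F,caucasian,1000,1200,90,420,490,95,460,645
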