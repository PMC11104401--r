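# ctxshift schema=1 task=discounting
"subject","session","context","version","trial","ss_amount","ll_amount","multiplier","delay","ll_on_left","choice","rt"
1,1,0,2,1,20,24,1.2,62,TRUE,1,NA
1,1,0,2,2,20,56,2.8,15,TRUE,1,NA
1,1,0,2,3,20,26.6,1.33,62,TRUE,0,NA
1,1,0,2,4,20,50,2.5,29,FALSE,1,NA
1,1,0,2,5,20,46,2.3,62,FALSE,1,NA
1,1,0,2,6,20,56,2.8,29,TRUE,1,NA
1,1,0,2,7,20,29.4,1.47,15,FALSE,1,NA
1,1,0,2,8,20,30,1.5,15,TRUE,1,NA
1,1,0,2,9,20,24,1.2,6,TRUE,0,NA
1,1,0,2,10,20,24,1.2,29,TRUE,1,NA
1,2,1,1,1,20,37,1.85,31,TRUE,0,NA
1,2,1,1,2,20,29,1.45,13,FALSE,0,NA
1,2,1,1,3,20,25,1.25,58,TRUE,0,NA
1,2,1,1,4,20,21,1.05,122,FALSE,0,NA
1,2,1,1,5,20,57,2.85,13,FALSE,1,NA
1,2,1,1,6,20,21,1.05,7,TRUE,1,NA
1,2,1,1,7,20,37,1.85,13,TRUE,0,NA
1,2,1,1,8,20,29,1.45,31,FALSE,0,NA
1,2,1,1,9,20,57,2.85,31,FALSE,1,NA
1,2,1,1,10,20,51,2.55,122,TRUE,0,NA
2,1,0,1,1,20,45,2.25,31,FALSE,0,NA
2,1,0,1,2,20,21.1,1.055,13,TRUE,1,NA
2,1,0,1,3,20,33,1.65,1,FALSE,1,NA
2,1,0,1,4,20,29,1.45,13,FALSE,1,NA
2,1,0,1,5,20,69,3.45,58,FALSE,0,NA
2,1,0,1,6,20,31,1.55,13,FALSE,0,NA
2,1,0,1,7,20,23,1.15,13,FALSE,0,NA
2,1,0,1,8,20,21,1.05,58,FALSE,0,NA
2,1,0,1,9,20,61,3.05,7,FALSE,1,NA
2,1,0,1,10,20,77,3.85,13,TRUE,1,NA
2,2,1,2,1,20,46,2.3,6,TRUE,1,NA
2,2,1,2,2,20,36.6,1.83,62,FALSE,0,NA
2,2,1,2,3,20,20.5,1.025,6,TRUE,0,NA
2,2,1,2,4,20,20.5,1.025,118,TRUE,0,NA
2,2,1,2,5,20,24,1.2,2,FALSE,1,NA
2,2,1,2,6,20,29.4,1.47,118,TRUE,0,NA
2,2,1,2,7,20,34,1.7,2,TRUE,1,NA
2,2,1,2,8,20,24,1.2,15,FALSE,0,NA
2,2,1,2,9,20,56,2.8,15,FALSE,1,NA
2,2,1,2,10,20,56,2.8,118,FALSE,0,NA
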