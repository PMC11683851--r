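score,cutoff,auc,tp,fp,tn,fn,sensitivity,specificity,ppv,npv,lr_pos,lr_neg,lr_consistent
PEDIA_early,3,0.80,218,2909,2852,16,0.93,0.50,6.97,99.44,1.84,0.14,TRUE
RISC_Malawi,7,0.78,159,1182,4579,75,0.68,0.79,11.86,98.39,3.31,0.40,TRUE
RISC,3,0.77,135,890,4871,99,0.58,0.85,13.17,98.01,3.73,0.50,TRUE
PEDIA_late,3,0.70,173,2114,3647,61,0.74,0.63,7.56,98.35,2.01,0.41,TRUE
LODS,1,0.69,116,801,4960,118,0.50,0.86,12.65,97.68,3.57,0.59,TRUE
WHO_emergency_signs,1,0.67,134,1754,4007,100,0.57,0.70,7.10,97.57,1.88,0.61,TRUE
Mpimbaza,5,0.67,60,157,5604,174,0.26,0.97,27.65,96.99,9.41,0.76,TRUE
FASTER,2,0.67,124,1378,4383,110,0.53,0.76,8.26,97.55,25.85,0.83,FALSE
TOPRS,2,0.64,170,3039,2722,64,0.73,0.47,5.30,97.70,1.82,0.76,FALSE
Brighton_PEWS,4,0.63,147,3186,2575,87,0.63,0.45,4.41,96.73,1.14,0.83,TRUE
ITAT,4,0.57,44,879,4882,190,0.19,0.85,4.77,96.25,1.23,0.96,TRUE
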