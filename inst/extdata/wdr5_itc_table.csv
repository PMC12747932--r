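protein,peptide,dH_kcal_mol,dH_se,minus_TdS_kcal_mol,N,KD_uM,KD_se_uM,detectable
WDR5,Kif2A_114-122,-15.7,0.13,7.48,0.91,0.78,0.05,TRUE
WDR5,Kif2A_114-122_R117A,NA,NA,NA,NA,NA,NA,FALSE
WDR5,Kif2A_114-120,-9.2,0.11,2.26,1.19,6.71,0.32,TRUE
WDR5,Kif2A_114-122_S121G,-10.6,0.14,3.29,0.94,3.72,0.23,TRUE
WDR5,Kif2A_114-122_S121A,-13.0,0.12,5.36,0.97,2.16,0.11,TRUE
WDR5_Y191F,Kif2A_114-122,-9.0,0.08,0.92,1.27,0.96,0.07,TRUE
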