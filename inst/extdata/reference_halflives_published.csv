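# Published early/late half-lives (h) of mitochondrial mRNAs and nuclear controls
# under long-term transcription inhibition (EtBr, IMT1B). Negative values mean the
# abundance increased over the window. early_two_point_fallback marks the early fit
# that used only the 0- and 5-h timepoints because the 2-h measurement increased.
transcript,condition,t_early_half,t_late_half,early_two_point_fallback
MT-ATP6,EtBr,3.92,4.19,FALSE
MT-ATP8,EtBr,4.32,4.34,FALSE
MT-CO1,EtBr,2.40,4.92,FALSE
MT-CO2,EtBr,2.31,4.73,FALSE
MT-CO3,EtBr,2.29,3.68,FALSE
MT-CYB,EtBr,2.86,5.14,FALSE
MT-ND1,EtBr,2.40,6.99,FALSE
MT-ND2,EtBr,2.50,7.09,FALSE
MT-ND3,EtBr,1.77,5.07,FALSE
MT-ND4,EtBr,4.96,4.61,FALSE
MT-ND4L,EtBr,3.72,4.80,FALSE
MT-ND5,EtBr,1.39,8.10,FALSE
MT-ND6,EtBr,1.84,34.40,FALSE
NDUFA7,EtBr,207.81,45.83,TRUE
c-MYC,EtBr,-4.47,21.72,FALSE
MT-ATP6,IMT1B,3.03,5.65,FALSE
MT-ATP8,IMT1B,2.89,5.41,FALSE
MT-CO1,IMT1B,3.60,8.62,FALSE
MT-CO2,IMT1B,2.94,6.84,FALSE
MT-CO3,IMT1B,3.61,5.93,FALSE
MT-CYB,IMT1B,1.94,8.24,FALSE
MT-ND1,IMT1B,1.29,10.15,FALSE
MT-ND2,IMT1B,1.14,13.43,FALSE
MT-ND3,IMT1B,1.79,7.59,FALSE
MT-ND4,IMT1B,3.16,6.64,FALSE
MT-ND4L,IMT1B,2.61,6.06,FALSE
MT-ND5,IMT1B,1.34,10.46,FALSE
MT-ND6,IMT1B,0.91,51.05,FALSE
NDUFA7,IMT1B,145.62,83.55,FALSE
c-MYC,IMT1B,-5.17,13.37,FALSE
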