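# Mean values (x) and standard deviations (sd) of classified nuclei per
# slide in the 92-smear oral screening study; used to parameterize the
# default synthetic slide composition (scaled down tenfold).
quantity,x,sd
normal_uncorrected_all,3426.00,3396.24
normal_corrected_all,2970.43,3186.11
abnormal_uncorrected_all,148.41,255.05
abnormal_corrected_all,119.65,223.80
abnormal_uncorrected_posFU,356.96,378.58
abnormal_corrected_posFU,313.64,328.89
abnormal_uncorrected_negFU,118.68,93.30
abnormal_corrected_negFU,43.70,93.30
pct_abnormal_all,5.25,13.30
n_9cEE_posFU,6,NA
mean_aneuploid_stemline_c_posFU,3.47,NA
pct_gt5_abnormal_posFU,68,NA
pct_gt4_abnormal_posFU,76,NA
pct_aneuploid_stemlines_posFU,56,NA
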