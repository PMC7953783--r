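# Reference table: phenotypic variance, variance-component ratios (fractions
# of phenotypic variance) and intra-herd heritability (with SE) for each
# trait, measured in the laboratory (instrument = lab) or predicted from
# Vis-NIRS / Micro-NIRS spectra. scale100 = TRUE flags variances printed
# multiplied by 100 (pH): natural-scale variance = phen_var / 100.
trait,instrument,phen_var,f_additive,f_batch,f_herd,f_residual,h2,h2_se,scale100
L,lab,11.64,0.23,0.18,0.06,0.54,0.30,0.09,FALSE
L,vis,9.96,0.32,0.15,0.06,0.46,0.41,0.10,FALSE
L,micro,9.74,0.28,0.15,0.05,0.52,0.35,0.11,FALSE
a,lab,3.12,0.09,0.25,0.11,0.55,0.14,0.07,FALSE
a,vis,1.83,0.04,0.31,0.11,0.53,0.08,0.07,FALSE
a,micro,1.52,0.04,0.22,0.10,0.64,0.07,0.05,FALSE
b,lab,2.79,0.10,0.23,0.08,0.59,0.14,0.07,FALSE
b,vis,1.88,0.02,0.26,0.08,0.64,0.04,0.04,FALSE
b,micro,1.67,0.04,0.16,0.07,0.73,0.05,0.06,FALSE
C,lab,4.71,0.09,0.25,0.10,0.56,0.14,0.07,FALSE
C,vis,3.01,0.03,0.30,0.10,0.58,0.04,0.05,FALSE
C,micro,2.46,0.03,0.21,0.10,0.65,0.05,0.05,FALSE
h,lab,4.17,0.10,0.21,0.06,0.62,0.14,0.07,FALSE
h,vis,2.81,0.03,0.24,0.06,0.67,0.05,0.06,FALSE
h,micro,2.59,0.09,0.18,0.07,0.67,0.11,0.08,FALSE
pH,lab,0.30,0.08,0.61,0.06,0.25,0.25,0.09,TRUE
pH,vis,0.13,0.08,0.48,0.07,0.37,0.18,0.08,TRUE
pH,micro,0.06,0.06,0.49,0.05,0.40,0.13,0.09,TRUE
PL,lab,1.39,0.10,0.14,0.05,0.71,0.13,0.07,FALSE
PL,vis,0.36,0.17,0.21,0.04,0.58,0.22,0.10,FALSE
PL,micro,0.28,0.10,0.16,0.15,0.69,0.13,0.07,FALSE
CL,lab,11.78,0.10,0.42,0.04,0.44,0.19,0.08,FALSE
CL,vis,2.07,0.03,0.54,0.04,0.40,0.07,0.06,FALSE
CL,micro,0.57,0.01,0.13,0.03,0.83,0.01,0.04,FALSE
WBSF,lab,113.14,0.16,0.42,0.06,0.37,0.31,0.10,FALSE
WBSF,vis,23.33,0.00,0.53,0.07,0.41,0.00,0.04,FALSE
WBSF,micro,15.41,0.05,0.40,0.07,0.48,0.10,0.07,FALSE
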