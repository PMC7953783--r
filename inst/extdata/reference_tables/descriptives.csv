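# Reference table: descriptive statistics of laboratory-measured meat quality
# traits and of their Vis-NIRS / Micro-NIRS predictions, with the external
# validation R2 of the calibration equations. One row per trait; pH on its
# natural scale; PL and CL in %, WBSF in N.
trait,n,mean_lab,sd_lab,mean_vis,sd_vis,r2ext_vis,mean_micro,sd_micro,r2ext_micro
L,1129,39.86,3.46,39.87,3.17,0.84,39.89,3.12,0.80
a,1133,28.59,1.74,28.60,1.34,0.55,28.62,1.22,0.52
b,1134,9.65,1.66,9.63,1.38,0.63,9.70,1.29,0.61
C,1133,30.19,2.15,30.18,1.73,0.58,30.22,1.56,0.55
h,1131,18.53,2.04,18.50,1.68,0.64,18.56,1.61,0.63
pH,1127,5.55,0.05,5.56,0.04,0.30,5.55,0.02,0.22
PL,1128,4.50,1.19,4.47,0.60,0.31,4.50,0.53,0.27
CL,1134,16.76,3.45,16.80,1.43,0.16,16.67,0.75,0.19
WBSF,1117,40.96,10.43,40.89,4.79,0.16,40.89,3.84,0.19
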