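# Reference table: additive genetic (r_a) and residual (r_e) correlations,
# with SEs, between each laboratory-measured trait and its Vis-NIRS or
# Micro-NIRS prediction, from bivariate animal-model analyses.
trait,instrument,r_a,r_a_se,r_e,r_e_se
L,vis,1.000,0.001,0.871,0.016
a,vis,0.958,0.173,0.671,0.029
b,vis,1.000,0.001,0.761,0.021
C,vis,1.000,0.001,0.703,0.024
h,vis,1.000,0.001,0.763,0.057
pH,vis,0.701,0.164,0.358,0.056
PL,vis,0.979,0.085,0.385,0.054
CL,vis,0.703,0.168,0.120,0.059
WBSF,vis,0.805,0.187,0.202,0.055
L,micro,1.000,0.001,0.831,0.022
a,micro,0.783,0.225,0.646,0.031
b,micro,0.930,0.189,0.598,0.025
C,micro,0.771,0.228,0.687,0.027
h,micro,0.858,0.134,0.756,0.026
pH,micro,0.448,0.256,0.262,0.028
PL,micro,0.879,0.162,0.378,0.045
CL,micro,0.248,0.271,0.265,0.058
WBSF,micro,0.418,0.316,0.271,0.070
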