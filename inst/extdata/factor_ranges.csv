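name,role,baseline,efast_lo,efast_hi,prcc_low_lo,prcc_low_hi,prcc_high_lo,prcc_high_hi
lambda,parameter,0.0755,0.062,0.093,0.062,0.084,0.062,0.093
V_G,parameter,1.2,0.1,1.56,0.1,1.47,0.1,1.56
K_G,parameter,19,5,24.7,5,24.7,5,24.7
n,parameter,0.001,0.0007,0.0013,0.0007,0.0012,0.0007,0.0013
delta,parameter,65,45.5,95,45.5,72,45.5,95
q,parameter,0.18,0.04,0.2,0.04,0.2,0.04,0.2
V_G3P,parameter,0.15,0.12,0.18,0.12,0.18,0.12,0.18
K_G3P,parameter,0.143,0.02,0.171,0.08,0.171,0.02,0.171
V_PYR,parameter,0.15,0.0013,0.3915,0.0013,0.3915,0.0013,0.243
K_PYR,parameter,1.7,0.05,2.21,0.05,2.21,0.66,2.21
beta,parameter,1,0.7,1.3,0.7,1.3,0.7,1.3
alpha,parameter,0.2,0.002,1,0.002,1,0.002,1
rho,parameter,0.05,0.04,0.0895,0.04,0.0895,0.04,0.0895
V_LACT,parameter,0.14,0.098,0.33,0.098,0.33,0.098,0.33
K_LACT,parameter,0.125,0.0875,10,0.0875,10,0.0875,10
V_ACoA,parameter,0.15,0.105,0.195,0.105,0.195,0.105,0.195
K_ACoA,parameter,0.02,0.005,0.026,0.005,0.026,0.005,0.026
phi,parameter,1,0.7,1.3,0.7,1.3,0.7,1.3
V_CIT,parameter,0.03,0.021,0.039,0.03,0.0326,0.021,0.032
K_CIT,parameter,0.0054,0.0046,0.00702,0.00531,0.0056,0.0046,0.00702
psi,parameter,8,6.4,9.6,6.4,9.6,7.68,8.57
kappa,parameter,10,7,13,9.84,10.2,7,13
gamma,parameter,1,0.7,1.3,1,1.07,0.7,1.3
G_E,parameter,11.5,5,20,5,20,5,20
L_E,parameter,10,5,22,10,22,10,12.22
G_0,initial_condition,NA,NA,NA,0.014,0.026,1.4,2.6
G3P_0,initial_condition,0,NA,NA,0,0.0001,0,0.0001
PYR_0,initial_condition,0,NA,NA,0,0.0001,0,0.0001
LACT_0,initial_condition,9.4,NA,NA,6.58,9.55,6.58,12.22
ACoA_0,initial_condition,0,NA,NA,0,0.0001,0,0.0001
CIT_0,initial_condition,0,NA,NA,0,0.0001,0,0.0001
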