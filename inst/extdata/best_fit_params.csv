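name,lo,hi,units,constraint_class,species
alpha_max,55.8,55.8,uM/s,fixed,mouse
alpha_ratio,5.51,5.51,,fixed,mouse
beta_dark,8.57,8.57,1/s,fixed,mouse
B_cG,1.8,1.8,,fixed,mouse
B_Ca,25.3,25.3,,fixed,mouse
k_GE,0.33,0.33,um^2/s,fixed,mouse
R_b,0.6,0.6,um,fixed,mouse
R_t,0.4,0.4,um,fixed,mouse
omega0,3.14159265358979,3.14159265358979,rad,fixed,mouse
D_cG,89.2,89.2,um^2/s,fixed,mouse
D_Ca,15,15,um^2/s,fixed,mouse
D_E,1.47,1.47,um^2/s,fixed,mouse
D_G,1.42,1.42,um^2/s,fixed,mouse
D_R,1.71,1.71,um^2/s,fixed,mouse
eps0,16.8,16.8,nm,fixed,mouse
F_const,96500,96500,C/mol,fixed,
f_Ca,0.26,0.26,,fixed,mouse
H,13.4,13.4,um,fixed,mouse
JcG_max,3138,3138,pA,fixed,mouse
Jex_sat,8.79,8.79,pA,fixed,mouse
kcat_Km,540,540,1/(uM s),fixed,mouse
k_R,87.1,87.1,1/s,fixed,mouse
k_E,82.3,82.3,1/s,fixed,mouse
K_cyc,134,134,nM,fixed,mouse
K_cG,14.2,14.2,uM,fixed,mouse
K_ex,0.4,0.4,uM,fixed,mouse
nu,0.65,0.65,,fixed,mouse
nu_RG,212,212,1/s,fixed,mouse
n_discs,400,400,,fixed,mouse
N_Av,6.02e23,6.02e23,1/mol,fixed,
m_cyc,2.3,2.3,,fixed,mouse
m_cG,2.9,2.9,,fixed,mouse
G_sigma,253.82,253.82,1/um^2,fixed,mouse
PDE_sigma,115,115,1/um^2,fixed,mouse
R_sigma,10000,10000,1/um^2,fixed,carp
sigma,1,1,,fixed,striped bass
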