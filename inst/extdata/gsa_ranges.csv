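name,lo,hi,units,constraint_class,species
R_b,0.585,0.615,um,gsa,mouse
R_t,0.38,0.42,um,gsa,mouse
H,12.7,14.1,um,gsa,mouse
omega0,2.51,3.77,rad,gsa,frog
eps0,16.4,17.2,nm,gsa,mouse
nu,0.61,0.71,,gsa,mouse
sigma,0.8,1.2,,gsa,striped bass
k_GE,0.05,1,um^2/s,gsa,carp
nu_RG,30,330,1/s,gsa,striped bass; carp
k_R,1,200,1/s,gsa,mouse rod
k_E,5,150,1/s,gsa,mouse
D_R,1,2,um^2/s,gsa,mouse rod
D_G,1.1,3.2,um^2/s,gsa,mouse rod
D_E,0.8,1.6,um^2/s,gsa,mouse rod
D_cG,50,196,um^2/s,gsa,mouse rod
D_Ca,12,18,um^2/s,gsa,mouse rod
G_sigma,200,1500,1/um^2,gsa,carp
PDE_sigma,10,120,1/um^2,gsa,carp
beta_dark,1,1000,1/s,gsa,carp
B_cG,1,2,,gsa,mouse rod
kcat_Km,190,1810,1/(uM s),gsa,frog rod
alpha_max,50,500,uM/s,gsa,striped bass; carp
a_min,0,1,,gsa,
m_cyc,2,2.5,,gsa,striped bass
K_cyc,130,140,nM,gsa,mouse
B_Ca,10,30,,gsa,mouse rod
JcG_max,1000,5000,pA,gsa,striped bass
m_cG,2,3.5,,gsa,striped bass
K_cG,10,30,uM,gsa,mouse rod
f_Ca,0.2,0.35,,gsa,striped bass
Jex_sat,1,10,pA,gsa,striped bass
K_ex,0.02,5,uM,gsa,striped bass
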