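name,lo,hi,units,constraint_class,species
k_GE,0.05,1,um^2/s,soft,carp
nu_RG,30,330,1/s,soft,striped bass; carp
k_R,1,200,1/s,soft,mouse rod
k_E,5,150,1/s,soft,mouse
D_R,1,2,um^2/s,soft,mouse rod
D_G,1.2,3.2,um^2/s,soft,mouse rod
D_E,0.8,1.6,um^2/s,soft,mouse rod
D_cG,50,196,um^2/s,soft,mouse rod
G_sigma,500,1500,1/um^2,soft,carp
PDE_sigma,10,100,1/um^2,soft,carp
beta_dark,1,1000,1/s,soft,carp
B_cG,1,2,,soft,mouse rod
kcat_Km,190,1810,1/(uM s),soft,frog rod
alpha_max,50,500,uM/s,soft,striped bass; carp
alpha_ratio,2,20,,soft,carp
m_cyc,2,2.5,,soft,striped bass
K_cyc,130,140,nM,soft,mouse
B_Ca,10,30,,soft,mouse rod
JcG_max,1000,5000,pA,soft,striped bass
m_cG,2.5,3.5,,soft,striped bass
K_cG,10,30,uM,soft,mouse rod
f_Ca,0.2,0.35,,soft,striped bass
Jex_sat,1,10,pA,soft,striped bass
K_ex,0.02,5,uM,soft,striped bass
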