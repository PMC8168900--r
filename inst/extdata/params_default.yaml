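# Model kinetic parameters. Units: days, g/cm^3, cm.
# Values not printed in the main model description are flagged PLACEHOLDER.
theta: 0.5  # [g/cm^3] constant combined density of all cells in the tumor  # PLACEHOLDER
C_M: 1.2  # [g/cm^3] cancer-cell logistic carrying capacity  # PLACEHOLDER
M0: 0.1  # [g/cm^3] naive monocyte/macrophage pool (constant)  # PLACEHOLDER
D0: 0.01  # [g/cm^3] naive dendritic-cell pool (constant)  # PLACEHOLDER
T10: 0.006  # [g/cm^3] naive CD4+ T-cell pool (constant)  # PLACEHOLDER
T80: 0.002  # [g/cm^3] inactive CD8+ T-cell pool (constant)  # PLACEHOLDER
lambda_C: 0.35  # [1/d] cancer-cell logistic growth rate  # PLACEHOLDER
mu_C: 0.17  # [1/d] cancer-cell death rate  # PLACEHOLDER
mu_T8C: 17  # [cm^3/(g*d)] killing rate of cancer cells by CD8+ T cells  # PLACEHOLDER
zeta_Tb: 400000  # [cm^3/g] TGF-beta inhibition of CD8 killing (cancer-specific)  # PLACEHOLDER
lambda_T1Tr: 6  # [1/d] Q-induced Th1 -> Treg conversion scale (cancer-specific)  # PLACEHOLDER
lambda_M2M1: 0.05  # [1/d] M2 -> M1 phenotype switch induced by IL-12  # PLACEHOLDER
lambda_M1M2: 0.05  # [1/d] M1 -> M2 phenotype switch induced by TGF-beta  # PLACEHOLDER
lambda_M1: 0.008  # [1/d] M1 activation from naive pool by CCL2  # PLACEHOLDER
lambda_M2: 0.024  # [1/d] M2/MDSC activation from naive pool by CCL2  # PLACEHOLDER
lambda_D: 0.08  # [1/d] dendritic-cell activation by tumor signal  # PLACEHOLDER
lambda_T1I12: 2.2  # [1/d] Th1 activation from naive pool by IL-12  # PLACEHOLDER
lambda_T8I12: 1.2  # [1/d] CD8 activation from inactive pool by IL-12  # PLACEHOLDER
lambda_TrTb: 0.15  # [1/d] TGF-beta-driven Treg differentiation from naive CD4 pool  # PLACEHOLDER
lambda_T1I2: 0.05  # [1/d] IL-2-induced Th1 proliferation  # PLACEHOLDER
lambda_T8I2: 0.1  # [1/d] IL-2-induced CD8 proliferation  # PLACEHOLDER
lambda_TrI2: 0.02  # [1/d] IL-2-induced Treg proliferation  # PLACEHOLDER
mu_M1: 0.02  # [1/d] M1 macrophage death rate  # PLACEHOLDER
mu_M2: 0.02  # [1/d] M2/MDSC death rate  # PLACEHOLDER
mu_D: 0.1  # [1/d] dendritic-cell death rate  # PLACEHOLDER
mu_T1: 0.197  # [1/d] Th1 death rate  # PLACEHOLDER
mu_T8: 0.18  # [1/d] CD8 death rate  # PLACEHOLDER
mu_Tr: 0.2  # [1/d] Treg death rate  # PLACEHOLDER
lambda_I2T1: 1.6e-08  # [1/d] IL-2 production by Th1 cells  # PLACEHOLDER
lambda_I10M2: 2.0e-09  # [1/d] IL-10 production by M2/MDSC  # PLACEHOLDER
lambda_I10C: 1.0e-10  # [1/d] IL-10 production by cancer cells  # PLACEHOLDER
lambda_I12D: 3.45e-08  # [1/d] IL-12 production by dendritic cells  # PLACEHOLDER
lambda_PC: 2.16e-09  # [1/d] CCL2 production by cancer cells  # PLACEHOLDER
lambda_TbC: 0.0015  # [1/d] TGF-beta production by cancer cells  # PLACEHOLDER
lambda_TbM2: 0.006  # [1/d] TGF-beta production by M2/MDSC  # PLACEHOLDER
lambda_TbTr: 0.5  # [1/d] TGF-beta production by Tregs  # PLACEHOLDER
lambda_PD: 6.25e-09  # [1/d] PD-1 expression by T cells (T1, T8, Tr)  # PLACEHOLDER
lambda_PL1: 5.0e-09  # [1/d] PD-L1 expression by T cells and macrophages  # PLACEHOLDER
lambda_PLC: 5.0e-10  # [1/d] PD-L1 expression by cancer cells  # PLACEHOLDER
mu_I2: 2.376  # [1/d] IL-2 degradation rate  # PLACEHOLDER
mu_I10: 8  # [1/d] IL-10 degradation rate  # PLACEHOLDER
mu_I12: 1.38  # [1/d] IL-12 degradation rate  # PLACEHOLDER
mu_P: 1.73  # [1/d] CCL2 degradation rate  # PLACEHOLDER
mu_Tb: 499  # [1/d] TGF-beta degradation rate  # PLACEHOLDER
mu_PD: 1  # [1/d] PD-1 turnover rate  # PLACEHOLDER
mu_PL: 1  # [1/d] PD-L1 turnover rate  # PLACEHOLDER
mu_A1: 0.2  # [1/d] anti-PD-1 antibody degradation rate  # PLACEHOLDER
mu_Ab: 0.2  # [1/d] anti-TGF-beta antibody degradation rate  # PLACEHOLDER
K_P: 5.0e-10  # [g/cm^3] CCL2 half-saturation for macrophage activation  # PLACEHOLDER
K_I12: 1.0e-10  # [g/cm^3] IL-12 half-saturation for activation  # PLACEHOLDER
K_Tb: 2.0e-06  # [g/cm^3] TGF-beta half-saturation  # PLACEHOLDER
K_I2: 4.0e-11  # [g/cm^3] IL-2 half-saturation for proliferation  # PLACEHOLDER
K_Q: 1.5e-08  # [g/cm^3] PD-1/PD-L1 complex half-saturation for Th1->Treg conversion  # PLACEHOLDER
K_C: 0.4  # [g/cm^3] tumor-signal half-saturation for DC activation  # PLACEHOLDER
Khat_TI10: 2.0e-11  # [g/cm^3] IL-10 inhibition constant on T-cell activation  # PLACEHOLDER
Khat_TTr: 0.002  # [g/cm^3] Treg inhibition constant on T-cell activation  # PLACEHOLDER
Khat_TQ: 1.0e-10  # [g/cm^3] PD-1/PD-L1 complex inhibition constant on T cells  # PLACEHOLDER
sigma: 10000000000.0  # [cm^3/g] PD-1/PD-L1 complex formation scale, Q = sigma*PD*PL  # PLACEHOLDER
mu_PDA1: 100000000  # [cm^3/(g*d)] PD-1 blocking rate by anti-PD-1 (mirrored depletion)  # PLACEHOLDER
mu_AbTb: 2000000000  # [cm^3/(g*d)] TGF-beta depletion rate by anti-TGF-beta  # PLACEHOLDER
mu_TbAb: 800000  # [cm^3/(g*d)] anti-TGF-beta consumption rate while blocking  # PLACEHOLDER
delta_C: 8.64e-07  # [cm^2/d] cancer-cell diffusivity  # PLACEHOLDER
delta_M: 8.64e-07  # [cm^2/d] macrophage diffusivity  # PLACEHOLDER
delta_T: 8.64e-07  # [cm^2/d] T-cell diffusivity  # PLACEHOLDER
delta_D: 8.64e-07  # [cm^2/d] dendritic-cell diffusivity  # PLACEHOLDER
delta_I2: 0.0864  # [cm^2/d] IL-2 diffusivity  # PLACEHOLDER
delta_I10: 0.0864  # [cm^2/d] IL-10 diffusivity  # PLACEHOLDER
delta_I12: 0.0864  # [cm^2/d] IL-12 diffusivity  # PLACEHOLDER
delta_P: 0.0864  # [cm^2/d] CCL2 diffusivity  # PLACEHOLDER
delta_Tb: 0.0864  # [cm^2/d] TGF-beta diffusivity  # PLACEHOLDER
delta_PD: 8.64e-07  # [cm^2/d] PD-1 diffusivity (membrane-bound, cell-like)  # PLACEHOLDER
delta_PL: 8.64e-07  # [cm^2/d] PD-L1 diffusivity (membrane-bound, cell-like)  # PLACEHOLDER
delta_A1: 0.036  # [cm^2/d] anti-PD-1 antibody diffusivity  # PLACEHOLDER
delta_Ab: 0.036  # [cm^2/d] anti-TGF-beta antibody diffusivity  # PLACEHOLDER
chi_P: 10  # [cm^5/(g*d)] chemotactic coefficient toward CCL2 (M1, M2, Tr)  # PLACEHOLDER
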